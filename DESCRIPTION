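Package: targetAE
Title: Predicting Drug Adverse Events from Target-Matched Comparator Safety Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts which of a fixed vocabulary of labeled adverse events a
    recently approved ("test") drug will carry, using the accumulated safety
    record of marketed "comparator" drugs that share the same pharmacological
    action (agonist or antagonist) at one or more of the same molecular
    targets. For every (comparator, test drug, adverse event) association five
    features are assembled - comparator label presence, comparator literature
    presence, MACCS/Tanimoto structural similarity (with a -1 sentinel for
    biologics), cosine similarity of trivalent target-action vectors, and
    comparator time on market - and a per-adverse-event Naive Bayes classifier
    turns comparator evidence into votes that are aggregated at a configurable
    threshold. Performance is characterized as bootstrap distributions of
    sensitivity, specificity, PPV and NPV (mode/median/quartiles), adverse
    events are classified as well- or poorly-predicted by the PPV mode, and
    leave-one-out cross-validation scores the ability to anticipate
    post-approval safety label changes. A seeded synthetic-data generator with
    planted target-to-event associations makes the whole pipeline testable
    without proprietary label data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), e1071, ChemmineR, ChemmineOB, jsonlite, optparse
Config/testthat/edition: 3
biocViews: Software, Classification, Pharmacogenomics
RoxygenNote: 7.3.3
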