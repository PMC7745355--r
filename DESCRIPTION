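Package: lncEnsemble
Title: Feature Ensemble Learning for Long Non-Coding RNA Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies transcripts as long non-coding RNAs (lncRNAs) or
    protein-coding transcripts from sequence alone. Encodes transcripts into
    six feature families (ORF/peptide/codon-usage descriptors, k-mer spectrum,
    reverse-complement k-mer, mismatch profiles, pseudo nucleotide
    composition, and auto-cross covariance of physicochemical property
    tracks), selects discriminative columns per family by ANOVA ranking
    followed by minimum-redundancy maximum-relevance search, and fuses the
    families with either an iteratively stacked random-forest ensemble or a
    softmax-attention embedding network trained by backpropagation. Includes
    stratified cross-validation with sensitivity/specificity/accuracy/AUC
    reporting and a seeded synthetic transcript generator that reproduces the
    ORF and codon-usage contrast between the two classes for download-free
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ranger,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'acc.R'
    'anel.R'
    'evaluation.R'
    'extract.R'
    'iel.R'
    'kmer-profiles.R'
    'orf.R'
    'pipeline.R'
    'psenc.R'
    'selection.R'
    'sequence-io.R'
    'synthetic.R'
    'tables.R'
    'transcript-features.R'
    'utils.R'
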