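Package: gazealign
Title: Fusing Eye Movements and Spoken Narratives for Image Region Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns co-captured eye-movement fixation sequences and time-stamped
    spoken-narrative transcripts with unsupervised bitext word alignment (IBM
    Model 1 and an HMM aligner with agreement training and posterior decoding),
    in order to label perceptually important image regions with the words
    observers use for them. Includes mean-shift fixation clustering and k-means
    image segmentation for defining visual units, linguistic-unit extraction
    from part-of-speech tagged transcripts, sliding-window parallel-corpus
    construction under a visual-linguistic ratio, evaluation against
    sure/possible reference alignments (precision, recall, alignment error
    rate) with simultaneous and fixed-delay temporal baselines, and a
    synthetic scanpath-and-narrative simulator with known word-region ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
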