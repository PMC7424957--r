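# gazealign

Label perceptually important image regions with the words observers use for
them, by fusing co-captured eye movements and spoken narratives with
unsupervised bitext word alignment.

When people view an image and describe it aloud, fixations point at the
regions that matter and words name what those regions contain — but the two
streams are asynchronous: an object is typically fixated a variable fraction
of a second before it is named, speakers revisit and re-describe, and many
words ground in no region at all. `gazealign` treats the ordered sequence of
fixated region labels and the ordered sequence of content words as a
parallel "bitext" and learns which words translate which regions with the
machinery of statistical machine translation: IBM Model 1 expectation
maximization, an HMM aligner with jump-dependent transitions and NULL
states, two-direction agreement training, and posterior decoding at a
threshold (default 0.1). It is aimed at researchers in visual cognition,
psycholinguistics, and multimodal data analysis who have eye-tracker
fixation logs and word-level time-stamped transcripts (or want to simulate
them) and need region-level semantic annotations plus a principled
evaluation.

The pipeline:

1. **Visual units** — parse raw tracker samples into fixations, drop
   observers with poor calibration (beyond *k* SD of the group mean in
   either direction), group pooled fixations into regions with mean-shift
   clustering (no preset cluster count; k-means image segmentation over
   RGB + spatial features and external label maps are alternatives), and
   encode each fixation by its region label.
2. **Linguistic units** — keep adjectives, nouns, proper nouns, gerunds, and
   foreign words from POS-tagged transcripts; remove stopwords,
   task-instruction words, and per-image singleton word forms.
3. **Parallel corpus** — cut each trial with a sliding window (*T* = 5 s,
   stride 0.5 s), merge contiguous identical visual units (e.g. `cluster3
   cluster2 cluster2 cluster3` → `cluster3 cluster2 cluster3`), and balance
   each window's visual side to β × (number of linguistic units), keeping
   the longest-duration fixations (α = longest).
4. **Alignment** — train both directions (2 iterations of Model 1, then 2 of
   the HMM) with agreement; decode every observer's whole-trial pair and
   pool distinct (word, region) links.
5. **Evaluation and annotation** — score against sure/possible reference
   alignments with precision = |A∩P*|/|A|, recall = |A∩S|/|S|, and

       AER = 1 − (|A∩S| + |A∩P*|) / (|A| + |S|),

   compare with simultaneous and 1-second-delay temporal baselines, and
   export ranked word labels per region.

A synthetic-observer module generates co-registered scanpaths and narratives
with known word–region ground truth (250 ms mean fixations, ~22 s narratives
at ~2.5 words/s, a Gaussian eye–voice lag of 0.9 ± 0.3 s, lexical diversity
with observer-idiosyncratic word choices), so the whole pipeline is testable
end to end without any recordings.

## Worked example

```r
library(gazealign)

ds <- simulate_dataset(n_images = 2, n_observers = 6, seed = 1)
ev <- evaluate_dataset(ds)
print(ev$summary, digits = 3)
#>         method precision recall    aer n_images
#> 1    framework     0.811  1.000 0.1075        2
#> 2 simultaneous     0.885  1.000 0.0635        2
#> 3      delayed     0.277  0.571 0.6266        2
```

Each row macro-averages two images. The framework recovers every sure
word–region pair (recall 1.00) at AER 0.11; the 1-second-delay baseline,
which matches each word to the region fixated one second earlier, reaches
only 0.57 recall at AER 0.63. The simultaneous baseline is near ceiling
*under these simulated conditions* — the generator's eye–voice lag is
tightly concentrated and shorter than naming dwells, so "word now, region
now" is usually right; with real recordings the lag is longer-tailed and
neither temporal rule holds up (see the vignette).

```r
ev$improvement[, c("baseline", "images", "n_recall", "n_aer", "d_recall", "d_aer")]
#>       baseline images n_recall n_aer d_recall d_aer
#> 1 simultaneous      2        0     0      0.0 -4.39
#> 2      delayed      2        2     2     42.9 51.91
```

The framework strictly improves recall and AER over the delay baseline on
both images (by 42.9 and 51.9 percentage points). The learned translation
lexicon also identifies every region's dominant name here
(`mean(ev$lexicon$recovered)` is 1.0), and ranked annotations are one call
away:

```r
run <- ev$runs[["img01"]]
freq <- table(unlist(lapply(run$lunits, `[[`, "surface")))
head(aggregate_labels(run$links, freq), 3)
#>      region rank  word count posterior
#> 1 cluster10    1 horse     2 0.6127093
#> 2 cluster11    1 field     3 0.9250916
#> 3 cluster12    1  ball     2 0.5741727
```

i.e. the cluster of fixations that the simulator generated around the
"horse" region is annotated *horse*, with the word's utterance count and
maximum link posterior.

The same pipeline runs stage by stage from a shell (each stage reads its
predecessor's files and writes a manifest):

```sh
Rscript inst/cli/gazealign simulate --out run --seed 1
Rscript inst/cli/gazealign run-all  --out run --seed 1
cat run/metrics_summary.tsv
```

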