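#!/usr/bin/env Rscript
# Regenerates inst/extdata/synthetic_csuq_responses.csv: a SYNTHETIC
# stand-in for a 30-respondent x 16-item usability survey on a 7-point
# Likert scale (the real responses are not published). One-factor model:
# each respondent has a latent satisfaction score; items load on it
# equally, with loadings chosen so the scale's expected internal
# consistency lands in the "excellent" range: with loading 1.5 and noise
# sd 1.77 the inter-item correlation is ~0.42, i.e. alpha ~ 0.92 for 16
# items by the Spearman-Brown prophecy.
set.seed(20240301)
n <- 30; k <- 16
latent <- rnorm(n)
m <- sapply(seq_len(k), function(j)
  pmin(7L, pmax(1L, as.integer(round(5 + 1.5 * latent + rnorm(n, 0, 1.77))))))
colnames(m) <- sprintf("q%02d", seq_len(k))
out <- file.path("inst", "extdata", "synthetic_csuq_responses.csv")
write.csv(as.data.frame(m), out, row.names = FALSE, quote = FALSE)
alpha <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
cat(sprintf("wrote %s (alpha = %.3f)\n", out, alpha))
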