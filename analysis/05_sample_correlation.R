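#!/usr/bin/env Rscript
# Stage 5: pairwise sample-correlation structure.
#
# Spearman rank correlations between all 24 runs summarize technical and
# biological reproducibility: technical replicates should correlate more
# strongly than biological replicates, which in turn exceed between-group
# correlations. Each coefficient also gets the parametric ellipse glyph
# (x, y) = (cos(theta + d/2), cos(theta - d/2)) with cos(d) = rho used in
# corrgram-style displays.

suppressMessages(library(lfqnest))

prep_tab <- read.delim("results/preprocessed_matrix.tsv", check.names = FALSE)
E <- as.matrix(prep_tab[, -1])

R <- spearman_matrix(E)
write_correlation_matrix(R, "results/sample_correlation.tsv")

# example glyph for the strongest off-diagonal pair
off <- R; diag(off) <- NA
best <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
glyph <- ellipse_coordinates(R[best[1], best[2]], n_points = 64)
write_glyph(glyph, "results/ellipse_example.tsv")

pairs_of <- function(cond) mean(off[cond], na.rm = TRUE)
ann <- sample_annotations()
same_block <- outer(paste(ann$age, ann$condition, ann$bio_rep),
                    paste(ann$age, ann$condition, ann$bio_rep), "==")
same_group <- outer(paste(ann$age, ann$condition),
                    paste(ann$age, ann$condition), "==")
cat(sprintf("mean Spearman rho: technical replicate pairs %.3f, biological %.3f, between-group %.3f\n",
            pairs_of(same_block), pairs_of(same_group & !same_block),
            pairs_of(!same_group)))
cat(sprintf("example glyph: rho = %.3f between %s and %s (d = %.3f rad)\n",
            glyph$rho, rownames(R)[best[1]], colnames(R)[best[2]], glyph$d))
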