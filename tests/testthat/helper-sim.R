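# Shared small-world fixtures, built in code.

# A compact 2-HG x 2-subgenome world: 4 chromosomes, enough loci for
# pipeline behaviour without full-genome cost.
small_world <- function(seed_genome = 61, seed_pop = 62, error_rate = 0,
                        missing_rate = 0.02, loci = 22, n = 164, ...) {
  g <- make_genome(n_hg = 2, n_subgenomes = 2, loci_per_chromosome = loci,
                   lengths_cM = c(80, 90), seed = seed_genome, ...)
  pop <- simulate_population(g, n_individuals = n, error_rate = error_rate,
                             missing_rate = missing_rate, seed = seed_pop)
  anchors <- data.frame(locus = g$loci$locus, ref_chrom = g$loci$ref_chrom,
                        ref_pos = g$loci$ref_pos, stringsAsFactors = FALSE)
  list(genome = g, pop = pop, anchors = anchors,
       chrom_lengths = stats::setNames(g$chromosomes$length_bp,
                                       g$chromosomes$ref_chrom)[
                                         !duplicated(g$chromosomes$ref_chrom)])
}

# Orientation-free Kendall tau of a mapped LG's bin representatives against
# the true chromosome positions.
lg_tau <- function(gm, truth, lg) {
  m <- gm$map[gm$map$LG == lg & gm$map$class == "codominant_1_2_1", ]
  reps <- m[!duplicated(m$bin), ]
  if (nrow(reps) < 3) return(NA_real_)
  abs(stats::cor(reps$position_cM, truth$cM[match(reps$locus, truth$locus)],
                 method = "kendall"))
}
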