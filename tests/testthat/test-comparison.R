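make_toy_map <- function(n = 20, lg = "LG01") {
  data.frame(locus = sprintf("m%02d", 1:n), HG = "Fvb1", LG = lg,
             position_cM = seq(0, 95, length.out = n),
             bin = sprintf("m%02d", 1:n), class = "codominant_1_2_1",
             phase = "coupling", stringsAsFactors = FALSE)
}

test_that("collinearity statistics detect order, orientation and inversions", {
  map <- make_toy_map()
  anchors <- data.frame(locus = map$locus, ref_chrom = "Fvb1",
                        ref_pos = seq(1e5, 2e6, length.out = 20))
  cs <- collinearity_stats(map, anchors)
  expect_equal(cs$per_lg$rho, 1)
  expect_equal(cs$per_lg$n_inversions, 0)
  expect_null(cs$inversions)

  # reversed LG: |rho| = 1 with negative sign
  rev_anchors <- anchors
  rev_anchors$ref_pos <- rev(anchors$ref_pos)
  cs_rev <- collinearity_stats(map, rev_anchors)
  expect_equal(cs_rev$per_lg$rho, -1)
  expect_equal(cs_rev$per_lg$n_inversions, 0)   # orientation-normalised

  # 5-locus inversion in the middle
  inv_anchors <- anchors
  inv_anchors$ref_pos[8:12] <- rev(inv_anchors$ref_pos[8:12])
  cs_inv <- collinearity_stats(map, inv_anchors)
  expect_equal(cs_inv$per_lg$n_inversions, 1)
  expect_equal(cs_inv$inversions$n_loci, 5)

  # < 3 anchors: flagged undefined
  cs_few <- collinearity_stats(map, anchors[1:2, ])
  expect_false(cs_few$per_lg$defined)

  # shuffled anchors: |rho| near 0
  set.seed(5)
  shuf <- anchors
  shuf$ref_pos <- sample(shuf$ref_pos)
  expect_lt(abs(collinearity_stats(map, shuf)$per_lg$rho), 0.5)
})

test_that("collinearity flags an injected inversion in a simulated map", {
  g <- make_genome(n_hg = 1, n_subgenomes = 2, loci_per_chromosome = 25,
                   lengths_cM = 100, fraction_specific = 1,
                   inversion = list(chrom = "HG1.1", n_loci = 5), seed = 81)
  pop <- simulate_population(g, n_individuals = 164, error_rate = 0,
                             missing_rate = 0, seed = 82)
  anch <- data.frame(locus = g$loci$locus, ref_chrom = g$loci$ref_chrom,
                     ref_pos = g$loci$ref_pos)
  gm <- build_map(pop$genotypes, anchors = anch)
  cs <- collinearity_stats(gm, anch)
  inv_lg <- gm$map$LG[match(g$loci$locus[g$loci$chrom == "HG1.1"][1],
                            gm$map$locus)]
  expect_gte(cs$per_lg$n_inversions[cs$per_lg$LG == inv_lg], 1)
})

test_that("coverage ratio follows the anchored-span definition", {
  map <- make_toy_map(3)
  anchors <- data.frame(locus = map$locus, ref_chrom = "Fvb1",
                        ref_pos = c(5, 50, 95))
  lens <- c(Fvb1 = 100)
  cov <- coverage_ratio(map, anchors, lens)
  expect_equal(cov$coverage_pct, 90)

  # full span and single anchor
  anchors$ref_pos <- c(1, 50, 101)
  expect_equal(coverage_ratio(map, anchors, lens)$coverage_pct, 100)
  cov1 <- coverage_ratio(map, anchors[2, ], lens)
  expect_equal(cov1$coverage_pct, 0)
  expect_false(cov1$defined)

  # monotone non-decreasing as anchors are added
  set.seed(6)
  full <- data.frame(locus = make_toy_map(20)$locus, ref_chrom = "Fvb1",
                     ref_pos = sort(sample(1:1000, 20)))
  lens2 <- c(Fvb1 = 1000)
  covs <- vapply(2:20, function(k) {
    coverage_ratio(make_toy_map(20), full[1:k, ], lens2)$coverage_pct
  }, numeric(1))
  expect_true(all(diff(covs) >= 0))

  # unknown chromosome length errors by name
  expect_error(coverage_ratio(map, anchors, c(FvbX = 9)), "Fvb1")
})

test_that("homoeolog-specific dropout reduces coverage of the affected LG", {
  base <- small_world(seed_genome = 83, seed_pop = 84)
  dropped_g <- make_genome(n_hg = 2, n_subgenomes = 2,
                           loci_per_chromosome = 22, lengths_cM = c(80, 90),
                           dropout = list(chrom = "HG1.1", fraction = 0.5),
                           seed = 83)
  pop_d <- simulate_population(dropped_g, n_individuals = 164,
                               error_rate = 0, missing_rate = 0.02,
                               seed = 84)
  anch_d <- data.frame(locus = dropped_g$loci$locus,
                       ref_chrom = dropped_g$loci$ref_chrom,
                       ref_pos = dropped_g$loci$ref_pos)
  gm_b <- build_map(base$pop$genotypes, anchors = base$anchors)
  gm_d <- build_map(pop_d$genotypes, anchors = anch_d)
  cov_of <- function(gm, g, anch, chrom) {
    first <- g$loci$locus[g$loci$chrom == chrom][1]
    lg <- gm$map$LG[match(first, gm$map$locus)]
    lens <- stats::setNames(g$chromosomes$length_bp, g$chromosomes$ref_chrom)
    lens <- lens[!duplicated(names(lens))]
    cov <- coverage_ratio(gm, anch, lens)
    cov$coverage_pct[cov$LG == lg]
  }
  expect_lt(cov_of(gm_d, dropped_g, anch_d, "HG1.1"),
            cov_of(gm_b, base$genome, base$anchors, "HG1.1") - 20)
})

test_that("haploSNP tallies and A/B labelling follow the rules", {
  map <- rbind(make_toy_map(10, "LG01"), make_toy_map(4, "LG02"))
  map$locus[11:14] <- sprintf("x%02d", 1:4)
  map$bin[11:14] <- map$locus[11:14]
  flags <- data.frame(
    locus = c(map$locus[1:10], map$locus[11:12]),
    vesca_match = c(rep(TRUE, 10), FALSE, FALSE),
    iinumae_match = c(rep(FALSE, 10), FALSE, TRUE))
  tal <- tally_haplosnps(map, flags)
  expect_equal(tal$YN[tal$LG == "LG01"], 10)
  expect_equal(tal$NN[tal$LG == "LG02"], 1)
  expect_equal(tal$NY[tal$LG == "LG02"], 1)
  # tallies sum to flagged mapped loci
  expect_equal(tal$YN + tal$YY + tal$NY + tal$NN, tal$n_flagged)
  expect_identical(tal$label[tal$LG == "LG01"], "A")
  expect_identical(tal$label[tal$LG == "LG02"], "B_I")

  # tie in Y-N: both LGs labelled A; invariant to input row order
  flags3 <- data.frame(locus = c(map$locus[1:2], map$locus[11:12]),
                       vesca_match = TRUE, iinumae_match = FALSE)
  tal3 <- tally_haplosnps(map, flags3)
  expect_true(all(tal3$label == "A"))
  set.seed(8)
  tal3b <- tally_haplosnps(map[sample(nrow(map)), ],
                           flags3[sample(nrow(flags3)), ])
  expect_identical(tal3b[order(tal3b$LG), "label"],
                   tal3[order(tal3$LG), "label"])

  # no flags: all-zero tallies
  tal0 <- tally_haplosnps(map, flags[0, ])
  expect_true(all(tal0$YN + tal0$YY + tal0$NY + tal0$NN == 0))
})

test_that("map commonality computes exact intersections", {
  mc <- map_commonality(m1 = c("a", "b", "c"), m2 = c("b", "c", "d"),
                        m3 = c("c", "e"))
  expect_equal(mc$common_all, 1)
  expect_equal(mc$pairwise$n_shared, c(2, 1, 1))
  expect_equal(unname(mc$specific), c(1, 1, 1))
  # inclusion-exclusion on the union
  union_size <- length(unique(c("a", "b", "c", "b", "c", "d", "c", "e")))
  ie <- sum(mc$n) - sum(mc$pairwise$n_shared) + mc$common_all
  expect_equal(ie, union_size)

  ident <- map_commonality(s1 = letters[1:4], s2 = letters[1:4])
  expect_equal(ident$common_all, 4)
  disj <- map_commonality(s1 = c("a"), s2 = c("b"), s3 = c("c"))
  expect_equal(disj$common_all, 0)
  expect_equal(sum(disj$pairwise$n_shared), 0)
})

test_that("depth comparison: t-test, modes, and degenerate cases", {
  # identical depth lists: t = 0, p = 1
  d0 <- data.frame(locus = letters[1:20],
                   depth = rep(c(10, 20, 30, 40, 50), 4),
                   class = rep(c("NMH", "PHR"), each = 10))
  dc0 <- depth_comparison(d0)
  expect_equal(dc0$t, 0)
  expect_equal(dc0$p_value, 1)

  # textbook two-sample t with known variance structure
  d1 <- data.frame(locus = 1:20, depth = c(rep(50, 10), rep(60, 10)),
                   class = rep(c("PHR", "NMH"), each = 10))
  d1$depth <- d1$depth + rep(c(-1, 1), 10)   # sd = 1 within class
  dc1 <- depth_comparison(d1)
  sp2 <- (9 * var(d1$depth[1:10]) + 9 * var(d1$depth[11:20])) / 18
  t_manual <- (mean(d1$depth[11:20]) - mean(d1$depth[1:10])) /
    sqrt(sp2 * (1 / 10 + 1 / 10))
  expect_equal(abs(dc1$t), abs(t_manual))
  expect_equal(dc1$df, 18)

  # one class empty -> undefined, flagged
  expect_false(depth_comparison(d1[d1$class == "PHR", ])$defined)

  # simulated probe depths: NMH mean higher, NMH multi-modal
  g <- make_genome(n_hg = 2, n_subgenomes = 2, loci_per_chromosome = 150,
                   fraction_specific = 0.5, seed = 91)
  dep <- simulate_read_depths(g$loci, lambda = 50, seed = 92)
  dc <- depth_comparison(dep)
  expect_gt(dc$means[["NMH"]], dc$means[["PHR"]])
  expect_lt(dc$p_value, 0.001)
  expect_gte(count_depth_modes(dep$depth[dep$class == "NMH"], adjust = 0.5),
             2)
  expect_equal(count_depth_modes(dep$depth[dep$class == "PHR"]), 1)
})

test_that("annual mutation estimate is rate times genome size", {
  expect_equal(annual_mutation_estimate(708e6), 10.62)
  expect_equal(annual_mutation_estimate(720e6), 10.8)
  expect_equal(annual_mutation_estimate(1e9, rate = 2e-8), 20)
})

test_that("TSV round trips preserve the genotype matrix", {
  w <- small_world(loci = 4, n = 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_matrix(w$pop$genotypes, path)
  back <- read_genotype_matrix(path)
  expect_identical(back, w$pop$genotypes)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tI1", "l1\tAC"), bad)
  expect_error(read_genotype_matrix(bad), "invalid genotype calls")
})
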