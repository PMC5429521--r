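# Calls of a 3x3 joint count table as two aligned vectors.
table_to_calls <- function(tab) {
  lev <- c("AA", "AB", "BB")
  a <- character(0); b <- character(0)
  for (i in 1:3) for (j in 1:3) {
    a <- c(a, rep(lev[i], tab[i, j]))
    b <- c(b, rep(lev[j], tab[i, j]))
  }
  list(a = a, b = b)
}

test_that("estimate_r handles the canonical trivial cases", {
  co <- rep(c("AA", "AB", "BB"), c(41, 82, 41))
  fit <- estimate_r(co, co)
  expect_equal(fit$r_hat, 0, tolerance = 1e-7)
  expect_identical(fit$phase, "coupling")
  expect_gt(fit$lod, 10)
  expect_equal(fit$n_informative, 164)

  # perfectly co-segregating but relabelled: repulsion, same r
  sw <- ifelse(co == "AA", "BB", ifelse(co == "BB", "AA", co))
  fit_r <- estimate_r(co, sw)
  expect_equal(fit_r$r_hat, 0, tolerance = 1e-7)
  expect_identical(fit_r$phase, "repulsion")

  # joint counts = product of margins: independent, r = 0.5, lod = 0
  tab <- outer(c(1, 2, 1), c(1, 2, 1)) * 4  # n = 64
  cl <- table_to_calls(tab)
  fit0 <- estimate_r(cl$a, cl$b)
  expect_equal(fit0$r_hat, 0.5, tolerance = 1e-6)
  expect_equal(fit0$lod, 0, tolerance = 1e-8)

  # no informative individuals -> undefined pair
  und <- estimate_r(c("AA", NA), c(NA, "AB"))
  expect_true(is.na(und$r_hat))
  expect_equal(und$n_informative, 0)
})

test_that("EM matches the exhaustive grid-search ML oracle on random tables", {
  set.seed(101)
  n_fail <- 0
  for (case in seq_len(120)) {
    tab <- oracle_random_table()
    if (sum(tab) < 2) next
    cl <- table_to_calls(tab)
    fit <- estimate_r(cl$a, cl$b)
    oracle <- oracle_grid_r(tab)
    agree <- abs(fit$r_hat - oracle$r) <= 1e-4 ||
      abs(fit$loglik - oracle$ll) <= 1e-9   # ML ties across phases
    if (!agree) n_fail <- n_fail + 1
  }
  expect_equal(n_fail, 0)
})

test_that("estimate_r recovers r for dominant locus types", {
  set.seed(103)
  g <- make_genome(n_hg = 1, n_subgenomes = 1, loci_per_chromosome = 2,
                   lengths_cM = 20, spacing = "even", fraction_specific = 1,
                   seed = 13)
  pop <- simulate_population(g, n_individuals = 3000, error_rate = 0,
                             missing_rate = 0, seed = 14)
  a <- pop$genotypes[1, ]
  b <- pop$genotypes[2, ]
  d <- diff(g$loci$cM)
  r_true <- (1 - exp(-2 * d / 100)) / 2
  # same gametes observed through a dominant lens: mask one homozygote
  b_dom <- ifelse(b == "AA", "AB", b)
  fit_cd <- estimate_r(a, b_dom, type_a = "codominant",
                       type_b = "dominant_AB_BB")
  expect_equal(fit_cd$r_hat, r_true, tolerance = 0.05)
  a_dom <- ifelse(a == "BB", "AB", a)
  fit_dd <- estimate_r(a_dom, b_dom, type_a = "dominant_AB_AA",
                       type_b = "dominant_AB_BB")
  expect_equal(fit_dd$r_hat, r_true, tolerance = 0.12)
})

test_that("batch pairwise estimation agrees with the single-pair path", {
  g <- make_genome(n_hg = 1, n_subgenomes = 1, loci_per_chromosome = 8,
                   lengths_cM = 60, fraction_specific = 1, seed = 15)
  pop <- simulate_population(g, n_individuals = 164, error_rate = 0,
                             missing_rate = 0.02, seed = 16)
  ps <- estimate_r_matrix(pop$genotypes)
  for (row in sample(nrow(ps), 10)) {
    single <- estimate_r(pop$genotypes[ps$a[row], ],
                         pop$genotypes[ps$b[row], ])
    expect_equal(ps$r_hat[row], single$r_hat, tolerance = 1e-6)
    expect_equal(ps$lod[row], single$lod, tolerance = 1e-6)
    expect_identical(ps$phase[row], single$phase)
  }
})

test_that("Haldane mapping function and inverse behave", {
  expect_equal(haldane_cm(0), 0)
  expect_equal(haldane_cm(0.2), -50 * log(0.6))
  r <- seq(0.01, 0.49, by = 0.02)
  expect_equal(haldane_r(haldane_cm(r)), r, tolerance = 1e-10)
  expect_error(haldane_cm(0.5), "0.5")
  expect_equal(haldane_cm(0.5, cap = TRUE), haldane_cm(0.4999))
})

test_that("coupling conversion is an involution that preserves r", {
  g <- make_genome(n_hg = 1, n_subgenomes = 1, loci_per_chromosome = 4,
                   lengths_cM = 30, fraction_specific = 1, seed = 17)
  pop <- simulate_population(g, n_individuals = 164, seed = 18)
  m <- pop$genotypes
  phases <- setNames(c("coupling", "repulsion", "repulsion", "coupling"),
                     rownames(m))
  m1 <- convert_to_coupling(m, phases)
  expect_identical(convert_to_coupling(m1, phases), m)   # involution
  expect_false(identical(m1, m))
  # AB and missing untouched
  expect_identical(m1 == "AB", m == "AB")
  expect_identical(is.na(m1), is.na(m))
  # relabelling leaves r_hat unchanged, phase becomes coupling
  f0 <- estimate_r(m[1, ], m[2, ])
  f1 <- estimate_r(m1[1, ], m1[2, ])
  expect_equal(f0$r_hat, f1$r_hat, tolerance = 1e-7)
  all_ab <- matrix("AB", 1, 10, dimnames = list("x", NULL))
  expect_identical(convert_to_coupling(all_ab, c(x = "repulsion")), all_ab)
})

test_that("grouping forms connected components deterministically", {
  g <- make_genome(n_hg = 2, n_subgenomes = 1, loci_per_chromosome = 20,
                   lengths_cM = 100, fraction_specific = 1, seed = 19)
  pop <- simulate_population(g, n_individuals = 164, error_rate = 0,
                             missing_rate = 0, seed = 20)
  ps <- estimate_r_matrix(pop$genotypes)
  grp <- group_loci(ps, rownames(pop$genotypes), lod_threshold = 5)
  expect_equal(length(grp), 2)
  truth_split <- split(g$loci$locus, g$loci$chrom)
  expect_setequal(grp[[1]], truth_split[[1]])
  expect_setequal(grp[[2]], truth_split[[2]])

  # infinite threshold -> all singletons; lone locus -> singleton group
  grp_inf <- group_loci(ps, rownames(pop$genotypes), lod_threshold = Inf)
  expect_equal(length(grp_inf), 40)
  single <- group_loci(ps[0, ], "only_locus")
  expect_identical(single, list(LG01 = "only_locus"))
})

test_that("ordering minimises SARF on an additive chain and recovers simulated order", {
  # 3-locus chain with known geometry
  ps <- data.frame(a = c("m1", "m2", "m1"), b = c("m2", "m3", "m3"),
                   r_hat = c(0.05, 0.05, 0.10), lod = 10,
                   stringsAsFactors = FALSE)
  expect_identical(order_group(c("m3", "m1", "m2"), ps), c("m1", "m2", "m3"))
  expect_identical(order_group("m1", ps), "m1")

  # 50-locus group at 2 cM spacing: Kendall tau vs truth >= 0.95
  g <- make_genome(n_hg = 1, n_subgenomes = 1, loci_per_chromosome = 50,
                   lengths_cM = 100, spacing = "even", fraction_specific = 1,
                   seed = 23)
  pop <- simulate_population(g, n_individuals = 164, error_rate = 0,
                             missing_rate = 0, seed = 24)
  ps <- estimate_r_matrix(pop$genotypes)
  ord <- order_group(rownames(pop$genotypes), ps)
  tau <- cor(match(ord, g$loci$locus), seq_along(ord), method = "kendall")
  expect_gte(abs(tau), 0.95)
})

test_that("solitary-missing imputation follows the flanking rule and is idempotent", {
  m <- rbind(l1 = c("AB", "AA", "AB"),
             l2 = c(NA,   NA,   "AB"),
             l3 = c("AB", "BB", NA))
  out <- impute_solitary_missing(m, list(c("l1", "l2", "l3")))
  expect_identical(unname(out["l2", 1]), "AB")  # flanks agree -> filled
  expect_true(is.na(out["l2", 2]))           # AA vs BB -> ambiguous
  expect_true(is.na(out["l3", 3]))           # terminal -> never imputed
  expect_identical(impute_solitary_missing(out, list(c("l1", "l2", "l3"))),
                   out)                      # fixed point
  # non-missing calls never altered
  expect_identical(out[!is.na(m)], m[!is.na(m)])
})

test_that("binning groups identical vectors and splits on any recombinant", {
  base <- rep(c("AA", "AB", "BB"), c(10, 20, 10))
  rec <- base
  rec[1] <- "AB"                              # one recombinant individual
  m <- rbind(a1 = base, a2 = base, a3 = rec)
  bins <- bin_loci(m)
  expect_identical(bins$bin[bins$locus == "a2"], "a1")   # duplicated locus
  expect_identical(bins$bin[bins$locus == "a3"], "a3")   # split
  # missing data: compared on jointly scored individuals only
  basem <- base; basem[5] <- NA
  m2 <- rbind(a1 = base, a2 = basem)
  expect_equal(length(unique(bin_loci(m2)$bin)), 1)
})

test_that("dominant loci attach to the nearest anchored bin", {
  map <- data.frame(locus = c("c1", "c2"), LG = "LG01",
                    position_cM = c(0, 10), bin = c("c1", "c2"),
                    class = "codominant_1_2_1", phase = "coupling",
                    stringsAsFactors = FALSE)
  anchors <- data.frame(locus = c("c1", "c2", "d1", "d2"),
                        ref_chrom = c("Fvb1", "Fvb1", "Fvb1", "Fvb9"),
                        ref_pos = c(900000, 1200000, 1000000, 5),
                        stringsAsFactors = FALSE)
  dom <- data.frame(locus = c("d1", "d2", "d3"),
                    class = "dominant_AB_BB_3_1", stringsAsFactors = FALSE)
  att <- attach_dominant_loci(map, dom, anchors)
  expect_equal(att$placed$position_cM[att$placed$locus == "d1"], 0)  # nearest
  expect_setequal(att$unplaced$locus, c("d2", "d3"))
  expect_identical(att$unplaced$reason[att$unplaced$locus == "d3"],
                   "no anchor")
  # exact tie -> smaller physical position wins
  anchors$ref_pos[3] <- 1050000
  att2 <- attach_dominant_loci(map, dom[1, , drop = FALSE], anchors)
  expect_identical(att2$placed$bin, "c1")
})
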