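#' Build a simulated allo-octoploid genome with known truth
#'
#' Constructs the stated world the rest of the pipeline is validated against:
#' an allopolyploid parent whose chromosomes come in `n_hg` homoeologous
#' groups (HGs) of `n_subgenomes` disomic chromosomes each (default 7 x 4,
#' the octoploid strawberry layout). Each locus lives on one host chromosome
#' and carries an [allele_config]: subgenome-specific loci are heterozygous in
#' the host subgenome only (`ABOOOOOO`-type); homoeologous loci additionally
#' carry fixed `B` alleles in 1-3 other subgenomes (`ABBBOOOO`-type).
#' Because the non-host copies are homozygous they never segregate, so only
#' host chromosomes need meiotic simulation.
#'
#' Reference anchors emulate a diploid ancestor assembly: all chromosomes of
#' an HG anchor collinearly to the same reference chromosome (`Fvb<hg>`), at
#' `bp_per_cM` physical bases per genetic centimorgan. Optional structural
#' variants: `inversion = list(chrom =, n_loci =)` reverses the reference
#' positions of a central run of loci on one chromosome;
#' `dropout = list(chrom =, fraction =)` deletes the distal fraction of one
#' chromosome's loci (emulating subgenome-specific absence).
#'
#' @param n_hg Number of homoeologous groups (default 7).
#' @param n_subgenomes Number of simulated chromosomes per HG (default 4).
#' @param loci_per_chromosome Loci per chromosome (default 36, giving ~1000
#'   loci at the default layout).
#' @param lengths_cM Genetic length of each HG's chromosomes, recycled to
#'   `n_hg`. The default for 7 HGs uses the mean per-HG linkage-group lengths
#'   reported for cultivated strawberry; otherwise 100 cM.
#' @param fraction_specific Fraction of loci given subgenome-specific
#'   (codominant-segregating) configurations; the remainder are homoeologous
#'   dominant loci. Default 0.78, the codominant share among mapped loci in
#'   the motivating dataset.
#' @param spacing `"uniform"` (positions drawn uniformly) or `"even"`
#'   (equispaced).
#' @param bp_per_cM Physical bases per centimorgan for the reference anchors.
#' @param inversion,dropout Optional structural variants, see Details.
#' @param seed RNG seed; the genome is deterministic given its arguments.
#' @return An object of class `sim_genome`: list with `chromosomes`
#'   (data.frame: chrom, hg, subgenome, length_cM, ref_chrom, length_bp) and
#'   `loci` (data.frame: locus, chrom, hg, subgenome, cM, config, phase_hom,
#'   true_class, ref_chrom, ref_pos).
#' @seealso [simulate_population], [simulate_meiosis]
#' @export
make_genome <- function(n_hg = 7, n_subgenomes = 4, loci_per_chromosome = 36,
                        lengths_cM = NULL,
                        fraction_specific = 0.78,
                        spacing = c("uniform", "even"),
                        bp_per_cM = 3e5,
                        inversion = NULL, dropout = NULL,
                        seed = 1) {
  spacing <- match.arg(spacing)
  if (is.null(lengths_cM)) {
    lengths_cM <- if (n_hg == 7) {
      c(78.8, 105.9, 111.5, 80.0, 95.5, 80.2, 92.5)
    } else rep(100, n_hg)
  }
  lengths_cM <- rep_len(lengths_cM, n_hg)
  stopifnot(n_hg >= 1, n_subgenomes >= 1, loci_per_chromosome >= 1,
            fraction_specific >= 0, fraction_specific <= 1)
  set.seed(seed)

  chromosomes <- expand.grid(subgenome = seq_len(n_subgenomes),
                             hg = seq_len(n_hg))[, 2:1]
  chromosomes$chrom <- sprintf("HG%d.%d", chromosomes$hg,
                               chromosomes$subgenome)
  chromosomes$length_cM <- lengths_cM[chromosomes$hg]
  chromosomes$ref_chrom <- sprintf("Fvb%d", chromosomes$hg)
  chromosomes$length_bp <- round(chromosomes$length_cM * bp_per_cM)
  rownames(chromosomes) <- NULL

  loci <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(ci) {
    ch <- chromosomes[ci, ]
    k <- loci_per_chromosome
    pos <- if (spacing == "even") {
      seq(0, ch$length_cM, length.out = k + 1L)[-1L] - ch$length_cM / (2 * k)
    } else sort(stats::runif(k, 0, ch$length_cM))
    specific <- stats::runif(k) < fraction_specific
    config <- character(k)
    for (i in seq_len(k)) {
      pairs <- rep("OO", 4L)
      pairs[ch$subgenome] <- "AB"
      if (!specific[i]) {
        n_bg <- sample(1:3, 1L)
        bg <- sample(setdiff(seq_len(4L), ch$subgenome), n_bg)
        pairs[bg] <- "BB"
      }
      config[i] <- paste(pairs, collapse = "")
    }
    data.frame(chrom = ch$chrom, hg = ch$hg, subgenome = ch$subgenome,
               cM = pos, config = config,
               phase_hom = sample(0:1, k, replace = TRUE),
               true_class = ifelse(specific, "codominant_1_2_1",
                                   "dominant_AB_BB_3_1"),
               ref_chrom = ch$ref_chrom,
               # deterministic per-subgenome offset keeps homoeologs distinct
               ref_pos = pmax(1L, round(pos * bp_per_cM) + ch$subgenome * 37L),
               stringsAsFactors = FALSE)
  }))
  loci$locus <- sprintf("L%05d", seq_len(nrow(loci)))
  loci <- loci[, c("locus", "chrom", "hg", "subgenome", "cM", "config",
                   "phase_hom", "true_class", "ref_chrom", "ref_pos")]
  rownames(loci) <- NULL

  if (!is.null(inversion)) {
    stopifnot(is.list(inversion), inversion$chrom %in% chromosomes$chrom)
    n_inv <- if (is.null(inversion$n_loci)) 5L else as.integer(inversion$n_loci)
    idx <- which(loci$chrom == inversion$chrom)
    if (length(idx) < n_inv) stop("inversion window larger than chromosome")
    start <- idx[max(1L, floor((length(idx) - n_inv) / 2))]
    win <- seq(start, start + n_inv - 1L)
    loci$ref_pos[win] <- rev(loci$ref_pos[win])
  }
  if (!is.null(dropout)) {
    stopifnot(is.list(dropout), dropout$chrom %in% chromosomes$chrom)
    frac <- if (is.null(dropout$fraction)) 0.5 else dropout$fraction
    ch_len <- chromosomes$length_cM[match(dropout$chrom, chromosomes$chrom)]
    drop <- loci$chrom == dropout$chrom & loci$cM > (1 - frac) * ch_len
    loci <- loci[!drop, , drop = FALSE]
    rownames(loci) <- NULL
  }

  structure(list(chromosomes = chromosomes, loci = loci,
                 bp_per_cM = bp_per_cM, seed = seed),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d chromosomes (%d HGs x %d subgenomes), %d loci\n",
              nrow(x$chromosomes), max(x$chromosomes$hg),
              max(x$chromosomes$subgenome), nrow(x$loci)))
  invisible(x)
}

#' Draw one explicit crossover gamete for a chromosome
#'
#' The crossover process is a homogeneous Poisson process with no
#' interference: the number of crossovers is Poisson with mean
#' `length_cM / 100` and breakpoints are uniform on the chromosome; the
#' starting homolog is chosen fairly. Used as the explicit reference for the
#' vectorised interval-parity sampler in [simulate_meiosis].
#'
#' @param length_cM Chromosome genetic length in centimorgans.
#' @return List with `start` (0/1 starting homolog) and `breaks` (sorted
#'   crossover positions in cM).
#' @export
crossover_gamete <- function(length_cM) {
  stopifnot(length_cM >= 0)
  n_xo <- stats::rpois(1L, length_cM / 100)
  list(start = sample(0:1, 1L),
       breaks = sort(stats::runif(n_xo, 0, length_cM)))
}

# Homolog source (0/1) at `positions` for one explicit gamete.
.gamete_source_at <- function(gamete, positions) {
  (gamete$start + vapply(positions, function(p) sum(gamete$breaks < p),
                         integer(1L))) %% 2L
}

#' Simulate gametes for every chromosome of a genome
#'
#' Draws `n` gametes per chromosome and returns, for each chromosome, an
#' `n x k` integer matrix of homolog sources (0/1) at the chromosome's locus
#' positions. Sampling uses the interval-parity representation of the
#' no-interference model: the source at the first locus is a fair coin and
#' flips between consecutive loci with the parity of a Poisson count with
#' mean `d/100` (d = inter-locus distance in cM) - exactly equivalent to
#' drawing Poisson crossovers with uniform breakpoints, because a homogeneous
#' Poisson process has independent counts on disjoint intervals.
#' Homoeologous chromosomes never exchange: each chromosome is sampled
#' independently.
#'
#' @param genome A [make_genome] object.
#' @param n Number of gametes.
#' @param seed Optional RNG seed.
#' @return Named list (by chromosome id) of `n x k` 0/1 matrices; columns
#'   are the chromosome's loci in map order.
#' @export
simulate_meiosis <- function(genome, n, seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (chrom in genome$chromosomes$chrom) {
    pos <- genome$loci$cM[genome$loci$chrom == chrom]
    if (!length(pos)) next
    src <- .sample_sources(pos, n)
    colnames(src) <- genome$loci$locus[genome$loci$chrom == chrom]
    out[[chrom]] <- src
  }
  out
}

# Alleles contributed by gametes with homolog sources `src` (n x k) for the
# loci of one chromosome. h0/h1 are the alleles carried by homolog 0/1.
.gamete_alleles <- function(src, h0, h1) {
  k <- ncol(src)
  al <- matrix("", nrow = nrow(src), ncol = k)
  for (j in seq_len(k)) al[, j] <- ifelse(src[, j] == 0L, h0[j], h1[j])
  al
}

#' Simulate a genotyped S1 (or F1) mapping population
#'
#' Produces the observed loci x individuals call matrix together with full
#' truth labels. Per individual and chromosome two gametes are drawn (both
#' from `genome` for S1 selfing; one from each parent for F1). The offspring
#' allele complement at each locus (two host-chromosome alleles plus the
#' constant homozygous background of any non-host subgenome copies) is
#' collapsed to the dosage-blind biallelic call AA/AB/BB, after which
#' genotyping error (replacement with a uniformly chosen different call, rate
#' `error_rate`) and missingness (rate `missing_rate`) are applied, in that
#' order.
#'
#' Defaults mirror the motivating S1 design: 164 individuals; error and
#' missing rates are small but nonzero stand-ins (no array error estimate is
#' available) of 0.005 and 0.02.
#'
#' @param genome Maternal [make_genome] object.
#' @param n_individuals Population size (default 164).
#' @param error_rate,missing_rate Per-call perturbation rates in \[0,1\].
#' @param population_type `"S1"` (selfing) or `"F1"` (requires
#'   `paternal_genome`).
#' @param paternal_genome For F1 crosses: a `sim_genome` with identical locus
#'   ids and positions (e.g. a modified copy of `genome` with different
#'   configurations/phases).
#' @param seed RNG seed; the simulation is bit-for-bit reproducible given
#'   `(genome, config, seed)`.
#' @return Object of class `sim_population`: list with `genotypes`
#'   (character matrix loci x individuals over AA/AB/BB/NA), `truth` (the
#'   genome's locus table), `genome`, and `config` (the simulation settings).
#' @export
simulate_population <- function(genome, n_individuals = 164,
                                error_rate = 0.005, missing_rate = 0.02,
                                population_type = c("S1", "F1"),
                                paternal_genome = NULL, seed = 1) {
  population_type <- match.arg(population_type)
  stopifnot(inherits(genome, "sim_genome"), n_individuals >= 2,
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (population_type == "F1") {
    if (is.null(paternal_genome)) {
      stop("F1 population requested without a paternal genome", call. = FALSE)
    }
    stopifnot(inherits(paternal_genome, "sim_genome"),
              identical(paternal_genome$loci$locus, genome$loci$locus),
              identical(paternal_genome$loci$cM, genome$loci$cM))
  } else {
    paternal_genome <- genome
  }
  set.seed(seed)

  loci <- genome$loci
  n_loci <- nrow(loci)
  calls <- matrix(NA_character_, nrow = n_loci, ncol = n_individuals,
                  dimnames = list(loci$locus,
                                  sprintf("I%03d", seq_len(n_individuals))))

  # homolog alleles and homozygous background per locus, per parent
  parent_parts <- function(g) {
    pr <- g$loci
    host <- pr$subgenome
    c1 <- substr(pr$config, 2L * host - 1L, 2L * host - 1L)
    c2 <- substr(pr$config, 2L * host, 2L * host)
    h0 <- ifelse(pr$phase_hom == 0L, c1, c2)
    h1 <- ifelse(pr$phase_hom == 0L, c2, c1)
    other <- vapply(seq_len(nrow(pr)), function(i) {
      s <- pr$config[i]
      paste0(substr(s, 1, 2 * host[i] - 2), substr(s, 2 * host[i] + 1, 8))
    }, character(1L))
    list(h0 = h0, h1 = h1,
         bgA = grepl("A", other, fixed = TRUE),
         bgB = grepl("B", other, fixed = TRUE))
  }
  mat <- parent_parts(genome)
  pat <- parent_parts(paternal_genome)

  for (chrom in genome$chromosomes$chrom) {
    idx <- which(loci$chrom == chrom)
    if (!length(idx)) next
    pos <- loci$cM[idx]
    src_m <- .sample_sources(pos, n_individuals)
    src_p <- .sample_sources(pos, n_individuals)
    al_m <- .gamete_alleles(src_m, mat$h0[idx], mat$h1[idx])
    al_p <- .gamete_alleles(src_p, pat$h0[idx], pat$h1[idx])
    bgA <- mat$bgA[idx] | pat$bgA[idx]
    bgB <- mat$bgB[idx] | pat$bgB[idx]
    for (j in seq_along(idx)) {
      has_a <- al_m[, j] == "A" | al_p[, j] == "A" | bgA[j]
      has_b <- al_m[, j] == "B" | al_p[, j] == "B" | bgB[j]
      calls[idx[j], ] <- ifelse(has_a & has_b, "AB",
                                ifelse(has_a, "AA", "BB"))
    }
  }

  if (error_rate > 0) {
    err <- matrix(stats::runif(length(calls)) < error_rate, nrow = n_loci)
    if (any(err)) {
      shift <- sample(1:2, sum(err), replace = TRUE)
      lev <- c("AA", "AB", "BB")
      cur <- match(calls[err], lev)
      calls[err] <- lev[(cur - 1L + shift) %% 3L + 1L]
    }
  }
  if (missing_rate > 0) {
    calls[matrix(stats::runif(length(calls)) < missing_rate,
                 nrow = n_loci)] <- NA_character_
  }

  structure(list(genotypes = calls, truth = loci, genome = genome,
                 config = list(n_individuals = n_individuals,
                               error_rate = error_rate,
                               missing_rate = missing_rate,
                               population_type = population_type,
                               seed = seed)),
            class = "sim_population")
}

# n gametes' homolog sources at ordered positions, via interval parity.
.sample_sources <- function(pos, n) {
  k <- length(pos)
  src <- matrix(0L, nrow = n, ncol = k)
  src[, 1L] <- sample(0:1, n, replace = TRUE)
  if (k > 1L) {
    d <- diff(pos)
    for (j in 2:k) {
      src[, j] <- (src[, j - 1L] + stats::rpois(n, d[j - 1L] / 100) %% 2L) %% 2L
    }
  }
  src
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d loci x %d individuals (%s, error=%g, missing=%g)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              x$config$population_type, x$config$error_rate,
              x$config$missing_rate))
  invisible(x)
}

#' Emulate Axiom-style array cluster classes from a call matrix
#'
#' Labels each locus with the genotype-cluster category an array pipeline
#' would assign from its call pattern: `CRBT` when the call rate is below
#' `call_rate_threshold` (checked first), `PHR` when all three genotype
#' calls are observed, `NMH` when exactly a heterozygote plus one homozygote
#' cluster is seen, `MHR` when a single call is observed, and `Other`
#' otherwise (e.g. both homozygotes but no heterozygote).
#'
#' @param genotypes Character matrix of calls (loci x individuals, NA =
#'   missing), or a `sim_population`.
#' @param call_rate_threshold Minimum call rate (default 0.97).
#' @return Named character vector of labels, one per locus.
#' @export
emulate_array_classes <- function(genotypes, call_rate_threshold = 0.97) {
  if (inherits(genotypes, "sim_population")) genotypes <- genotypes$genotypes
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 1)
  apply_names <- rownames(genotypes)
  out <- vapply(seq_len(nrow(genotypes)), function(i) {
    x <- genotypes[i, ]
    if (mean(!is.na(x)) < call_rate_threshold) return("CRBT")
    seen <- sort(unique(x[!is.na(x)]))
    if (length(seen) == 3L) "PHR"
    else if (identical(seen, c("AA", "AB")) || identical(seen, c("AB", "BB")))
      "NMH"
    else if (length(seen) == 1L) "MHR"
    else "Other"
  }, character(1L))
  names(out) <- apply_names
  out
}

#' Simulate probe read depths for mapped loci
#'
#' Emulates whole-genome reads mapped back onto probe sequences: a
#' subgenome-specific probe recruits reads from one genomic copy
#' (depth ~ Poisson(lambda)), while a homoeologous probe recruits from every
#' subgenome carrying the target, i.e. Poisson(k * lambda) with k = number of
#' present subgenomes (2-4, taken from each locus's true configuration).
#' Class labels follow the array emulation: specific loci are `PHR`-like,
#' homoeologous loci `NMH`-like.
#'
#' @param truth Locus truth table (from [make_genome]/[simulate_population]).
#' @param lambda Mean depth per genomic copy (default 57, the observed mean
#'   depth of codominant probes in the motivating dataset).
#' @param seed Optional RNG seed.
#' @return data.frame: locus, depth, class (`PHR`/`NMH`).
#' @export
simulate_read_depths <- function(truth, lambda = 57, seed = NULL) {
  if (inherits(truth, "sim_population")) truth <- truth$truth
  stopifnot(is.data.frame(truth), all(c("locus", "config") %in% names(truth)))
  if (!is.null(seed)) set.seed(seed)
  k <- vapply(truth$config, function(cfg) {
    pairs <- attr(allele_config(cfg), "pairs")
    sum(pairs[1L, ] != "O")
  }, integer(1L), USE.NAMES = FALSE)
  data.frame(locus = truth$locus,
             depth = stats::rpois(nrow(truth), k * lambda),
             class = ifelse(k == 1L, "PHR", "NMH"),
             stringsAsFactors = FALSE)
}
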