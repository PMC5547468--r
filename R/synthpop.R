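#' SNP panel constructor
#'
#' A SNP panel is the per-site description of the simulated variant universe:
#' one row per biallelic SNP with its chromosome label, 0-based coordinate and
#' alternate-allele frequency `f`. All downstream machinery (genotype
#' sampling, beacon construction, the beta fit behind the risk model) is
#' indexed against a panel.
#'
#' @param chrom Character vector of chromosome labels, one per SNP.
#' @param pos Integer vector of 0-based coordinates, strictly increasing
#'   within each chromosome.
#' @param f Numeric vector of alternate-allele frequencies, each strictly
#'   inside (0, 1): a panel catalogues polymorphic sites only.
#' @param population_size Optional number of diploid individuals the
#'   frequencies refer to; stored as an attribute for provenance.
#'
#' @return A tibble of class `snp_panel` with columns `chrom`, `pos`, `f`.
#' @export
#' @examples
#' snp_panel(chrom = "1", pos = 0:2, f = c(0.01, 0.2, 0.5))
snp_panel <- function(chrom, pos, f, population_size = NULL) {
  if (length(f) == 0) abort("a panel needs at least one SNP")
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0) || any(f >= 1)) {
    abort("all frequencies must be strictly inside (0, 1)")
  }
  chrom <- as.character(rep_len(chrom, length(f)))
  pos <- rep_len(as.integer(pos), length(f))
  if (any(pos < 0)) abort("positions must be non-negative (0-based)")
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) abort("(chrom, pos) pairs must be unique")
  ok <- tapply(pos, chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(ok))) abort("pos must be strictly increasing within a chromosome")
  out <- tibble(chrom = chrom, pos = pos, f = as.numeric(f))
  class(out) <- c("snp_panel", class(out))
  attr(out, "population_size") <- population_size
  out
}

#' Sample allele frequencies from the standard neutral spectrum
#'
#' Draws per-SNP alternate-allele frequencies from the standard neutral
#' site-frequency spectrum of a population of `population_size` diploids:
#' the derived-allele count \eqn{i \in \{1, \dots, 2M-1\}} is drawn with
#' probability proportional to \eqn{1/i} and the frequency is \eqn{f = i/2M}.
#' This is the spectrum whose beta fit underlies the risk model's `D_N`.
#'
#' @param num_snps Number of SNPs to draw.
#' @param population_size Number of diploid individuals `M` (so `2M`
#'   chromosomes); the spectrum support is `1/(2M), ..., (2M-1)/(2M)`.
#' @param seed Optional integer seed; identical seeds give identical panels.
#' @param chrom Chromosome label for the simulated panel (single label; the
#'   simulated genome is abstract and unlinked).
#'
#' @return An [snp_panel] with `num_snps` rows, positions `0:(num_snps-1)`.
#' @export
#' @examples
#' panel <- sample_neutral_frequencies(1000, population_size = 20000, seed = 1)
#' mean(panel$f)
sample_neutral_frequencies <- function(num_snps, population_size, seed = NULL,
                                       chrom = "1") {
  assert_count(num_snps, "num_snps")
  assert_count(population_size, "population_size", min = 2)
  two_m <- 2 * population_size
  counts <- with_seed_maybe(seed, {
    sample.int(two_m - 1, size = num_snps, replace = TRUE, prob = 1 / seq_len(two_m - 1))
  })
  snp_panel(chrom = chrom, pos = seq_len(num_snps) - 1L, f = counts / two_m,
            population_size = population_size)
}

#' Sample diploid genotypes for a panel
#'
#' Draws the alternate-allele dosage (0, 1 or 2 copies) of each individual at
#' each panel SNP independently as Binomial(2, f), i.e. Hardy-Weinberg
#' proportions with no linkage. Rows are individuals, columns SNPs.
#'
#' @param panel An [snp_panel].
#' @param num_individuals Number of diploid individuals to draw.
#' @param seed Optional integer seed.
#'
#' @return An integer matrix of class `genotype_matrix` (individuals x SNPs)
#'   with the panel attached as attribute `panel`.
#' @export
#' @examples
#' panel <- sample_neutral_frequencies(50, 1000, seed = 1)
#' g <- sample_genotypes(panel, 10, seed = 2)
#' table(g)
sample_genotypes <- function(panel, num_individuals, seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  assert_count(num_individuals, "num_individuals")
  m <- nrow(panel)
  g <- with_seed_maybe(seed, {
    # column-major fill: each column (SNP) shares its frequency
    matrix(stats::rbinom(num_individuals * m, 2L,
                         rep(panel$f, each = num_individuals)),
           nrow = num_individuals, ncol = m)
  })
  storage.mode(g) <- "integer"
  structure(g, class = c("genotype_matrix", "matrix", "array"), panel = panel)
}

#' Simulate a relative of a target genome
#'
#' Produces the genotype row of a relative with kinship-style sharing
#' coefficient `phi`: at each SNP, with probability `phi` the target's
#' genotype is copied, otherwise a fresh Binomial(2, f) genotype is drawn.
#' `phi = 1` is an identical twin, `0.5` parent-offspring/sibling, `0.25`
#' and `0.125` more distant relatives, `0` an unrelated individual.
#'
#' @param target_row Integer genotype vector (dosages 0/1/2), one entry per
#'   panel SNP.
#' @param panel The [snp_panel] the genotypes are indexed against.
#' @param phi Sharing probability in \[0, 1\].
#' @param seed Optional integer seed.
#'
#' @return An integer genotype vector of the same length as `target_row`.
#' @export
make_relative <- function(target_row, panel, phi, seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) || phi < 0 || phi > 1) {
    abort("`phi` must be a single number in [0, 1]")
  }
  target_row <- check_genotype_row(target_row, panel)
  with_seed_maybe(seed, {
    copied <- stats::runif(nrow(panel)) < phi
    fresh <- stats::rbinom(nrow(panel), 2L, panel$f)
    out <- ifelse(copied, target_row, fresh)
    as.integer(out)
  })
}

#' Degrade the adversary's copy of a genome with sequencing error
#'
#' Models the mismatch rate `delta` between the copy of the target genome the
#' adversary holds and the genome itself: each alternate-allele-carrying site
#' is independently reverted to homozygous reference with probability `delta`
#' (a missed variant call), so a beacon query at that site no longer reflects
#' the true genome. Sites without alternate alleles are unchanged.
#'
#' @param target_row Integer genotype vector (dosages 0/1/2).
#' @param delta Per-site reversion probability in \[0, 1).
#' @param seed Optional integer seed.
#'
#' @return The degraded integer genotype vector.
#' @export
apply_sequencing_error <- function(target_row, delta, seed = NULL) {
  assert_scalar_prob(delta, "delta", allow_one = FALSE)
  if (!is.numeric(target_row) || any(is.na(target_row)) ||
      !all(target_row %in% 0:2)) {
    abort("`target_row` must be a vector of dosages in {0, 1, 2}")
  }
  target_row <- as.integer(target_row)
  if (delta == 0) return(target_row)
  alt <- which(target_row > 0L)
  if (length(alt) == 0L) return(target_row)
  with_seed_maybe(seed, {
    drop <- alt[stats::runif(length(alt)) < delta]
    target_row[drop] <- 0L
    target_row
  })
}

check_genotype_row <- function(row, panel) {
  if (!is.numeric(row) || length(row) != nrow(panel) || any(is.na(row)) ||
      !all(row %in% 0:2)) {
    abort("genotype row must hold dosages in {0, 1, 2}, one per panel SNP")
  }
  as.integer(row)
}

#' Panel serialization
#'
#' Writes/reads a panel as tab-separated text with header columns
#' `chrom`, `pos`, `f`; positions are 1-based on disk (VCF convention) and
#' 0-based in memory. The round trip is exact.
#'
#' @param panel An [snp_panel].
#' @param path File path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` an
#'   [snp_panel].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  out <- tibble(chrom = panel$chrom, pos = panel$pos + 1L,
                f = format(panel$f, digits = 17))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    f = readr::col_double()), progress = FALSE)
  if (!all(c("chrom", "pos", "f") %in% names(tab))) {
    abort("panel file must have columns chrom, pos, f")
  }
  snp_panel(chrom = tab$chrom, pos = tab$pos - 1L, f = tab$f)
}

#' Genotype matrix serialization
#'
#' Stores a genotype matrix as a compact raw-byte container (one byte per
#' dosage) with a plain-text sidecar index (`<path>.idx`) recording the
#' dimensions, byte layout and the panel (inline TSV). The round trip is
#' exact.
#'
#' @param genotypes A `genotype_matrix` from [sample_genotypes()].
#' @param path File path for the binary container.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   the restored `genotype_matrix`.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  panel <- attr(genotypes, "panel")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(genotypes), con)  # column-major, one byte per cell
  idx <- c(
    "#beaconrisk genotype container v1",
    sprintf("rows\t%d", nrow(genotypes)),
    sprintf("cols\t%d", ncol(genotypes)),
    "layout\tcolumn-major uint8",
    "panel\tchrom,pos(1-based),f",
    sprintf("%s\t%d\t%s", panel$chrom, panel$pos + 1L, format(panel$f, digits = 17))
  )
  writeLines(idx, paste0(path, ".idx"))
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  idx <- readLines(paste0(path, ".idx"))
  if (!startsWith(idx[1], "#beaconrisk genotype container")) {
    abort("missing or unrecognized sidecar index")
  }
  rows <- as.integer(sub("rows\t", "", idx[2]))
  cols <- as.integer(sub("cols\t", "", idx[3]))
  body <- idx[-(1:5)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  panel <- snp_panel(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)) - 1L,
    f = as.numeric(vapply(parts, `[`, "", 3L))
  )
  raw <- readBin(path, what = "raw", n = rows * cols)
  g <- matrix(as.integer(raw), nrow = rows, ncol = cols)
  structure(g, class = c("genotype_matrix", "matrix", "array"), panel = panel)
}
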