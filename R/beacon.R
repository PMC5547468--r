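#' Beacon databases
#'
#' A beacon database is the unit a beacon web service answers from: a member
#' count `N` plus, for every catalogued `(chrom, pos, allele)` triple, a
#' presence bit saying whether the service answers "yes" there. Raw beacons
#' built from genotypes answer "yes" exactly where at least one member
#' carries the alternate allele; perturbed beacons (see
#' [perturb_eliminate_random()], [perturb_randomized_response()]) keep the
#' catalogue but may flip presence bits. Simulated panels use the abstract
#' allele token `"ALT"`; VCF-derived beacons use nucleotide alleles.
#'
#' @param catalog Tibble with columns `chrom` (character), `pos` (0-based
#'   integer), `allele` (character), `present` (logical).
#' @param N Number of member genomes (>= 1).
#' @param provenance `"raw"` or `"perturbed"`.
#' @param mechanism For perturbed beacons, a list of mechanism metadata.
#' @return An object of class `beacon_db`.
#' @export
beacon_db <- function(catalog, N, provenance = "raw", mechanism = NULL) {
  assert_count(N, "N")
  stopifnot(is.data.frame(catalog),
            all(c("chrom", "pos", "allele", "present") %in% names(catalog)))
  catalog <- as_tibble(catalog)
  if (!is.logical(catalog$present)) abort("`present` must be logical")
  if (!all(provenance %in% c("raw", "perturbed"))) {
    abort('`provenance` must be "raw" or "perturbed"')
  }
  structure(
    list(N = as.integer(N), catalog = catalog,
         provenance = provenance, mechanism = mechanism),
    class = "beacon_db"
  )
}

#' @export
print.beacon_db <- function(x, ...) {
  cat(sprintf("<beacon_db> N = %d members, %d catalogued triples (%d present), %s\n",
              x$N, nrow(x$catalog), sum(x$catalog$present), x$provenance))
  if (!is.null(x$mechanism)) {
    cat(sprintf("  mechanism: %s, bias = %g, epsilon = %g\n",
                x$mechanism$mechanism, x$mechanism$bias,
                x$mechanism$epsilon))
  }
  invisible(x)
}

beacon_key <- function(chrom, pos, allele) paste(chrom, pos, allele, sep = ":")

#' Build a beacon from a genotype matrix
#'
#' Catalogues every panel SNP (allele token `"ALT"`) and marks it present iff
#' at least one of the selected members carries one or more copies of the
#' alternate allele. Adding members never removes presence.
#'
#' @param genotypes A `genotype_matrix` from [sample_genotypes()].
#' @param member_indices Row indices of the beacon members (non-empty).
#' @return A `beacon_db` with `N = length(member_indices)`.
#' @export
#' @examples
#' panel <- sample_neutral_frequencies(100, 1000, seed = 1)
#' g <- sample_genotypes(panel, 20, seed = 2)
#' build_beacon(g, 1:10)
build_beacon <- function(genotypes, member_indices) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  member_indices <- unique(as.integer(member_indices))
  if (length(member_indices) == 0) abort("`member_indices` must be non-empty")
  if (any(member_indices < 1L | member_indices > nrow(genotypes))) {
    abort("`member_indices` out of range for the genotype matrix")
  }
  panel <- attr(genotypes, "panel")
  sub <- genotypes[member_indices, , drop = FALSE]
  present <- colSums(sub > 0L) > 0L
  catalog <- tibble(chrom = panel$chrom, pos = panel$pos,
                    allele = "ALT", present = as.logical(present))
  beacon_db(catalog, N = length(member_indices))
}

#' Query a beacon
#'
#' Pure yes/no lookup: `TRUE` iff the `(chrom, pos, allele)` triple is
#' catalogued and its presence bit is set. Positions not catalogued return
#' `FALSE` (public beacons answer "no" rather than erroring). Repeated
#' identical queries always return identical answers.
#'
#' @param db A `beacon_db`.
#' @param chrom,pos,allele Query triple(s); `pos` is 0-based. Vectorized.
#' @return Logical vector of answers.
#' @export
query_beacon <- function(db, chrom, pos, allele = "ALT") {
  stopifnot(inherits(db, "beacon_db"))
  allele <- as.character(allele)
  if (any(is.na(allele)) || any(!nzchar(allele)) ||
      any(!allele %in% c("A", "C", "G", "T", "ALT"))) {
    abort('`allele` must be one of "A", "C", "G", "T" or the token "ALT"')
  }
  n <- max(length(chrom), length(pos), length(allele))
  idx <- match(beacon_key(rep_len(as.character(chrom), n),
                          rep_len(as.integer(pos), n),
                          rep_len(allele, n)),
               beacon_key(db$catalog$chrom, db$catalog$pos, db$catalog$allele))
  ans <- db$catalog$present[idx]
  ans[is.na(ans)] <- FALSE
  ans
}

#' Beacon table serialization
#'
#' Writes/reads the beacon as tab-separated text: a `##N=<members>` header
#' line plus optional `##mechanism=` metadata, then a header row
#' `chrom pos allele present` and one row per catalogued triple. Positions
#' are 1-based on disk, 0-based in memory; `present` is 0/1. The round trip
#' is exact.
#'
#' @param db A `beacon_db`.
#' @param path File path.
#' @return `write_beacon()` returns `path` invisibly; `read_beacon()` a
#'   `beacon_db`.
#' @export
write_beacon <- function(db, path) {
  stopifnot(inherits(db, "beacon_db"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("##N=%d", db$N), con)
  writeLines(sprintf("##provenance=%s", db$provenance), con)
  if (!is.null(db$mechanism)) {
    writeLines(sprintf("##mechanism=%s;bias=%.17g;epsilon=%.17g",
                       db$mechanism$mechanism, db$mechanism$bias,
                       db$mechanism$epsilon), con)
  }
  writeLines("chrom\tpos\tallele\tpresent", con)
  writeLines(sprintf("%s\t%d\t%s\t%d", db$catalog$chrom, db$catalog$pos + 1L,
                     db$catalog$allele, as.integer(db$catalog$present)), con)
  invisible(path)
}

#' @rdname write_beacon
#' @export
read_beacon <- function(path) {
  lines <- readLines(path)
  meta <- grep("^##", lines)
  n_line <- grep("^##N=", lines)
  if (length(n_line) != 1) {
    abort(sprintf("beacon table %s: missing ##N= header line (expected at line 1)", path))
  }
  N <- as.integer(sub("^##N=", "", lines[n_line]))
  provenance <- "raw"
  p_line <- grep("^##provenance=", lines)
  if (length(p_line) == 1) provenance <- sub("^##provenance=", "", lines[p_line])
  mechanism <- NULL
  m_line <- grep("^##mechanism=", lines)
  if (length(m_line) == 1) {
    kv <- strsplit(sub("^##mechanism=", "", lines[m_line]), ";", fixed = TRUE)[[1]]
    mechanism <- list(
      mechanism = kv[1],
      bias = as.numeric(sub("^bias=", "", kv[2])),
      epsilon = as.numeric(sub("^epsilon=", "", kv[3]))
    )
  }
  body <- lines[-meta]
  if (length(body) == 0 || body[1] != "chrom\tpos\tallele\tpresent") {
    abort(sprintf("beacon table %s: missing column header at line %d",
                  path, length(meta) + 1L))
  }
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 4L)
  if (length(bad)) {
    abort(sprintf("beacon table %s: malformed row at line %d",
                  path, length(meta) + 1L + bad[1]))
  }
  present_raw <- vapply(rows, `[`, "", 4L)
  if (!all(present_raw %in% c("0", "1"))) {
    abort(sprintf("beacon table %s: `present` must be 0 or 1 (line %d)",
                  path, length(meta) + 1L + which(!present_raw %in% c("0", "1"))[1]))
  }
  catalog <- tibble(
    chrom = vapply(rows, `[`, "", 1L),
    pos = as.integer(vapply(rows, `[`, "", 2L)) - 1L,
    allele = vapply(rows, `[`, "", 3L),
    present = present_raw == "1"
  )
  beacon_db(catalog, N = N, provenance = provenance, mechanism = mechanism)
}

#' Build a beacon from a VCF file
#'
#' Reads an (optionally gzipped) VCF with GT genotype fields and catalogues
#' one `(chrom, pos, alt)` triple per alternate allele of each record,
#' present iff at least one sample genotype carries that allele.
#' Multi-allelic records are split per alternate allele. Records without GT
#' are skipped; the skip count is reported as a warning.
#'
#' @param path Path to the VCF file.
#' @return A `beacon_db` with `N` = number of samples.
#' @export
import_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) abort("VCF has no sample genotype (GT) data")
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  no_gt <- apply(gt, 1, function(r) all(is.na(r)))
  if (any(no_gt)) {
    warn(sprintf("skipped %d VCF site(s) with no GT calls", sum(no_gt)))
  }
  rows <- list()
  for (r in which(!no_gt)) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    # allele indices carried by any sample at this site
    calls <- unlist(strsplit(gt[r, !is.na(gt[r, ])], "[/|]"))
    carried <- suppressWarnings(unique(as.integer(calls)))
    carried <- carried[!is.na(carried) & carried > 0]
    for (k in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom = fix[r, "CHROM"],
        pos = as.integer(fix[r, "POS"]) - 1L,  # VCF is 1-based
        allele = alts[k],
        present = k %in% carried
      )
    }
  }
  catalog <- if (length(rows)) bind_rows(rows) else
    tibble(chrom = character(), pos = integer(),
           allele = character(), present = logical())
  beacon_db(catalog, N = ncol(gt))
}
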