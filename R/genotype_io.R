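# Genotype container, readers/writers, and marker quality control.
#
# Dosages are additively coded 0/1/2 = count of the second (alternate) allele
# at a biallelic marker; NA marks a missing genotype. The marker map carries
# 1-based physical bp positions; all marker/sample indices in R are 1-based.

MISSING_TOKENS <- c("NA", "-9", ".", "")

#' Construct a genotype matrix object
#'
#' Bundles a samples x markers dosage matrix with its marker map. This is the
#' raw substrate every other stage of the package consumes.
#'
#' @param dosages numeric/integer matrix, rows = samples, columns = markers;
#'   entries in \{0,1,2\} or `NA` for missing.
#' @param map data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   one row per marker column, positions non-decreasing within chromosome.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `rownames(dosages)`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (with dimnames set), `sample_ids`, and `map`.
#' @export
genotype_matrix <- function(dosages, map, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) {
    gv_validation_error("sample ids are required (rownames or `sample_ids`)")
  }
  sample_ids <- as.character(sample_ids)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- as.character(map$id)
  g <- structure(list(dosages = dosages, sample_ids = sample_ids, map = map),
                 class = "genotype_matrix")
  validate_genotype_matrix(g)
  g
}

#' Validate genotype-matrix invariants
#'
#' Checks dosage coding, dimension agreement, sample-id uniqueness, marker-id
#' uniqueness, and within-chromosome position ordering. Called by every
#' constructor; exported so simulated or hand-built objects can be audited.
#'
#' @param g a `genotype_matrix`.
#' @return `g`, invisibly.
#' @export
validate_genotype_matrix <- function(g) {
  d <- g$dosages
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    gv_validation_error("non-missing dosages must be 0, 1 or 2")
  }
  if (length(g$sample_ids) != nrow(d)) {
    gv_validation_error("sample_ids length does not match row count")
  }
  if (anyDuplicated(g$sample_ids)) {
    gv_validation_error(sprintf("duplicate sample id: %s",
                                g$sample_ids[duplicated(g$sample_ids)][1]))
  }
  if (nrow(g$map) != ncol(d)) {
    gv_validation_error("marker map length does not match column count")
  }
  if (!all(c("id", "chrom", "pos") %in% names(g$map))) {
    gv_validation_error("marker map needs columns id, chrom, pos")
  }
  if (anyDuplicated(g$map$id)) {
    gv_validation_error("duplicate marker ids in map")
  }
  if (any(g$map$pos < 0)) gv_validation_error("negative bp position")
  for (ch in unique(g$map$chrom)) {
    p <- g$map$pos[g$map$chrom == ch]
    if (is.unsorted(p)) {
      gv_validation_error(sprintf("positions not non-decreasing on chromosome %s", ch))
    }
  }
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%d chromosomes, %.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

default_map <- function(marker_ids) {
  data.frame(id = as.character(marker_ids), chrom = "1",
             pos = seq_along(marker_ids), stringsAsFactors = FALSE)
}

#' Read genotypes from TSV, PLINK .ped/.map, or PLINK --recode A (.raw)
#'
#' TSV dialect: header row of marker ids with a leading sample-id column;
#' cells in \{0,1,2\} with `NA`, `-9` or `.` for missing. `.ped/.map`:
#' dosage = count of the "second" allele, which is the lexicographically
#' later of the two alleles observed at that marker when the file supplies
#' no order; an allele pair containing `0` is missing. `.raw`: PLINK
#' additive recode with the six standard leading columns.
#'
#' Unparseable genotype tokens become missing and are counted in the
#' `parse_log` attribute rather than aborting the read.
#'
#' @param path file path (`.ped` file for `ped_map`).
#' @param format one of `"tsv"`, `"ped_map"`, `"raw"`.
#' @param map_path optional marker-map path; for `ped_map` defaults to the
#'   `.map` next to the `.ped`; for `tsv`/`raw` a 3-column TSV
#'   (id, chrom, pos) — if absent a single-chromosome map is synthesized.
#' @return a `genotype_matrix` with attribute `parse_log` (list with
#'   `n_unparseable`).
#' @export
read_genotypes <- function(path, format = c("tsv", "ped_map", "raw"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) gv_format_error(sprintf("file not found: %s", path))
  switch(format,
         tsv = read_genotypes_tsv(path, map_path),
         ped_map = read_genotypes_ped(path, map_path),
         raw = read_genotypes_raw(path, map_path))
}

read_lines_checked <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) gv_format_error(sprintf("empty file: %s", path))
  lines
}

parse_dosage_tokens <- function(tok) {
  # returns list(values, n_unparseable); missing tokens -> NA (not counted)
  v <- rep(NA_real_, length(tok))
  miss <- tok %in% MISSING_TOKENS
  num <- suppressWarnings(as.numeric(tok))
  ok <- !miss & !is.na(num) & num %in% c(0, 1, 2)
  v[ok] <- num[ok]
  list(values = v, n_unparseable = sum(!ok & !miss))
}

read_map_file <- function(map_path, n_markers_expected = NULL) {
  m <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(m) == 4) {            # PLINK .map: chrom id cM pos
    map <- data.frame(id = as.character(m[[2]]), chrom = as.character(m[[1]]),
                      pos = as.integer(m[[4]]), stringsAsFactors = FALSE)
  } else if (ncol(m) >= 3) {     # id chrom pos
    map <- data.frame(id = as.character(m[[1]]), chrom = as.character(m[[2]]),
                      pos = as.integer(m[[3]]), stringsAsFactors = FALSE)
  } else gv_format_error(sprintf("map file %s needs >= 3 columns", map_path))
  if (!is.null(n_markers_expected) && nrow(map) != n_markers_expected) {
    gv_format_error(sprintf("map has %d markers, genotypes have %d",
                            nrow(map), n_markers_expected))
  }
  map
}

read_genotypes_tsv <- function(path, map_path) {
  lines <- read_lines_checked(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) gv_format_error("TSV header must list marker ids after the sample-id column (line 1)")
  marker_ids <- header[-1]
  n_unp <- 0L
  rows <- vector("list", length(lines) - 1L)
  ids <- character(length(lines) - 1L)
  for (i in seq_along(rows)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header)) {
      gv_format_error(sprintf("line %d has %d fields, expected %d",
                              i + 1L, length(f), length(header)))
    }
    ids[i] <- f[1]
    p <- parse_dosage_tokens(f[-1])
    rows[[i]] <- p$values
    n_unp <- n_unp + p$n_unparseable
  }
  if (anyDuplicated(ids)) {
    gv_validation_error(sprintf("duplicate sample id: %s", ids[duplicated(ids)][1]))
  }
  d <- do.call(rbind, rows)
  map <- if (!is.null(map_path)) read_map_file(map_path, length(marker_ids)) else default_map(marker_ids)
  if (!identical(as.character(map$id), marker_ids)) map$id <- marker_ids
  g <- genotype_matrix(d, map, ids)
  attr(g, "parse_log") <- list(n_unparseable = n_unp)
  g
}

read_genotypes_ped <- function(path, map_path) {
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
  if (!file.exists(map_path)) gv_format_error(sprintf("map file not found: %s", map_path))
  map <- read_map_file(map_path)
  m <- nrow(map)
  lines <- read_lines_checked(path)
  n <- length(lines)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m) {
      gv_format_error(sprintf("line %d has %d fields, expected %d (6 + 2 x %d markers)",
                              i, length(f), 6 + 2 * m, m))
    }
    ids[i] <- f[2]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1, 2 * m, by = 2)]
    a2[i, ] <- al[seq(2, 2 * m, by = 2)]
  }
  if (anyDuplicated(ids)) {
    gv_validation_error(sprintf("duplicate sample id: %s", ids[duplicated(ids)][1]))
  }
  d <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(setdiff(unique(obs), "0"))   # lexicographic; "0" = missing
    if (length(alleles) > 2) {
      gv_format_error(sprintf("marker %s has >2 alleles", map$id[j]))
    }
    second <- if (length(alleles)) alleles[length(alleles)] else NA_character_
    miss <- a1[, j] == "0" | a2[, j] == "0"
    if (!is.na(second)) {
      d[, j] <- (a1[, j] == second) + (a2[, j] == second)
    }
    d[miss, j] <- NA_real_
  }
  g <- genotype_matrix(d, map, ids)
  attr(g, "parse_log") <- list(n_unparseable = 0L)
  g
}

read_genotypes_raw <- function(path, map_path) {
  lines <- read_lines_checked(path)
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(header) <= 6 || !identical(header[1:6], lead)) {
    gv_format_error("not a PLINK --recode A header (line 1)")
  }
  marker_ids <- sub("_[ACGT0-9]+$", "", header[-(1:6)])
  n_unp <- 0L
  n <- length(lines) - 1L
  ids <- character(n)
  d <- matrix(NA_real_, n, length(marker_ids))
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
    if (length(f) != length(header)) {
      gv_format_error(sprintf("line %d has %d fields, expected %d",
                              i + 1L, length(f), length(header)))
    }
    ids[i] <- f[2]
    p <- parse_dosage_tokens(f[-(1:6)])
    d[i, ] <- p$values
    n_unp <- n_unp + p$n_unparseable
  }
  if (anyDuplicated(ids)) {
    gv_validation_error(sprintf("duplicate sample id: %s", ids[duplicated(ids)][1]))
  }
  map <- if (!is.null(map_path)) read_map_file(map_path, length(marker_ids)) else default_map(marker_ids)
  g <- genotype_matrix(d, map, ids)
  attr(g, "parse_log") <- list(n_unparseable = n_unp)
  g
}

#' Write genotypes (and marker map) as TSV
#'
#' Inverse of `read_genotypes(format = "tsv")`: round-trips dosages, the
#' missingness mask and the marker map exactly.
#'
#' @param g a `genotype_matrix`.
#' @param path output TSV path for the dosage table.
#' @param map_path optional path for the 3-column marker map TSV.
#' @export
write_genotypes <- function(g, path, map_path = NULL) {
  d <- g$dosages
  lines <- c(paste(c("sample_id", g$map$id), collapse = "\t"),
             vapply(seq_len(nrow(d)), function(i) {
               v <- d[i, ]
               s <- ifelse(is.na(v), "NA", format(v, trim = TRUE, scientific = FALSE))
               paste(c(g$sample_ids[i], s), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  if (!is.null(map_path)) {
    utils::write.table(g$map[, c("id", "chrom", "pos")], map_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read / write a phenotype table
#'
#' TSV with a header: `sample_id` then one column per trait; missing values
#' allowed (`NA`).
#'
#' @param path file path.
#' @return data.frame with `sample_id` and numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(ph)[1] <- "sample_id"
  ph$sample_id <- as.character(ph$sample_id)
  if (anyDuplicated(ph$sample_id)) gv_validation_error("duplicate sample id in phenotype table")
  ph
}

#' @rdname read_phenotypes
#' @param ph phenotype data.frame.
#' @export
write_phenotypes <- function(ph, path) {
  utils::write.table(ph, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract one trait as a named numeric vector
#'
#' @param ph phenotype data.frame from [read_phenotypes()].
#' @param trait trait column name.
#' @return numeric vector named by sample id (missing phenotypes dropped).
#' @export
pheno_vector <- function(ph, trait) {
  if (!trait %in% names(ph)) gv_config_error(sprintf("trait '%s' not in phenotype table", trait))
  y <- ph[[trait]]
  names(y) <- ph$sample_id
  y[!is.na(y)]
}

# ---------------------------------------------------------------------------
# Quality control

#' Per-marker call rate
#'
#' Fraction of samples with a non-missing genotype.
#'
#' @param x dosage column (numeric with NA for missing).
#' @return fraction in \[0, 1\].
#' @export
marker_call_rate <- function(x) {
  if (!length(x)) gv_contract_error("empty dosage column")
  mean(!is.na(x))
}

#' Per-marker minor allele frequency
#'
#' `p = sum(dosages) / (2 * n_nonmissing)` is the frequency of the second
#' allele; the MAF is `min(p, 1 - p)`.
#'
#' @param x dosage column.
#' @return MAF in \[0, 0.5\].
#' @export
marker_maf <- function(x) {
  n <- sum(!is.na(x))
  if (n == 0) gv_stop("all genotypes missing: MAF undefined", "gvitgp_undefined_marker")
  p <- sum(x, na.rm = TRUE) / (2 * n)
  min(p, 1 - p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on the conditional distribution of the heterozygote
#' count given the allele counts (the Wigginton/PLINK exact test): the
#' p-value is the summed probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' A monomorphic marker returns 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (homozygous reference,
#'   heterozygous, homozygous alternate).
#' @return p-value in \[0, 1\].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) gv_contract_error("negative genotype count")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) gv_contract_error("no genotypes")
  rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (rare == 0) return(1.0)
  hets <- seq.int(rare %% 2, rare, by = 2)
  # log conditional probability up to a shared constant
  logp <- hets * log(2) - lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial((2 * n - rare - hets) / 2)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

marker_geno_counts <- function(x) {
  c(n_AA = sum(x == 0, na.rm = TRUE),
    n_Aa = sum(x == 1, na.rm = TRUE),
    n_aa = sum(x == 2, na.rm = TRUE))
}

#' Apply marker quality control
#'
#' Retains markers with call rate strictly above `cr_min`, minor allele
#' frequency strictly above `maf_min`, and exact HWE p-value strictly above
#' `hwe_min` (defaults: >95\%, >0.01, >1e-6). Idempotent: a clean panel is
#' returned unchanged.
#'
#' @param g a `genotype_matrix`.
#' @param cr_min,maf_min,hwe_min filter thresholds (strict inequalities).
#' @return list with `genotypes` (the surviving column subset, original
#'   order) and `report` (per-marker data.frame: id, call_rate, maf, hwe_p,
#'   passed, plus the thresholds as attributes).
#' @export
apply_qc <- function(g, cr_min = 0.95, maf_min = 0.01, hwe_min = 1e-6) {
  d <- g$dosages
  m <- ncol(d)
  cr <- colMeans(!is.na(d))
  maf <- rep(NA_real_, m)
  hwe <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    x <- d[, j]
    if (any(!is.na(x))) {
      maf[j] <- marker_maf(x)
      cts <- marker_geno_counts(x)
      hwe[j] <- hwe_exact_p(cts[1], cts[2], cts[3])
    }
  }
  passed <- !is.na(maf) & cr > cr_min & maf > maf_min & hwe > hwe_min
  report <- data.frame(id = g$map$id, call_rate = cr, maf = maf, hwe_p = hwe,
                       passed = passed, stringsAsFactors = FALSE)
  attr(report, "thresholds") <- c(cr_min = cr_min, maf_min = maf_min, hwe_min = hwe_min)
  if (!any(passed)) {
    gv_stop("no markers survive QC: downstream stages cannot run", "gvitgp_empty_panel_error")
  }
  keep <- which(passed)
  out <- genotype_matrix(d[, keep, drop = FALSE], g$map[keep, , drop = FALSE],
                         g$sample_ids)
  list(genotypes = out, report = report)
}

#' Write a QC report as TSV
#' @param report QC report from [apply_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a genotype matrix
#'
#' @param g a `genotype_matrix`.
#' @param samples sample ids (or NULL for all).
#' @param markers marker column indices (or NULL for all).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  rows <- if (is.null(samples)) seq_along(g$sample_ids) else match(samples, g$sample_ids)
  if (anyNA(rows)) gv_validation_error("unknown sample id in subset")
  cols <- if (is.null(markers)) seq_len(ncol(g$dosages)) else markers
  genotype_matrix(g$dosages[rows, cols, drop = FALSE],
                  g$map[cols, , drop = FALSE],
                  g$sample_ids[rows])
}
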