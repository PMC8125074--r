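#' Convert refractometry readings to buoyant density
#'
#' CsCl buoyant density from refractive index via the linear calibration
#' \eqn{\rho = 10.927\, n_c - 13.593} (AR200 refractometer convention).
#' Readings outside the plausible CsCl range \[1.33, 1.46\] trigger a
#' warning, not an error.
#'
#' @param n_c Refractive index (dimensionless), vectorized.
#' @return Buoyant density in g/ml.
#' @examples
#' refraction_to_density(1.4040)
#' @export
refraction_to_density <- function(n_c) {
  bad <- !is.finite(n_c)
  if (any(bad))
    stop("non-finite refractive index at position(s) ",
         paste(which(bad), collapse = ", "))
  out <- n_c < 1.33 | n_c > 1.46
  if (any(out))
    warning("refractive index outside plausible CsCl range [1.33, 1.46] ",
            "at position(s) ", paste(which(out), collapse = ", "))
  10.927 * n_c - 13.593
}

#' Invert the density calibration back to a refractive index
#' @param density Buoyant density in g/ml.
#' @return Refractive index.
#' @export
density_to_refraction <- function(density) {
  (density + 13.593) / 10.927
}

# Column names reserved for gradient metadata; everything else is an OTU.
.reserved_cols <- c("fraction", "n_c", "density", "dna_ng")

#' Construct a gradient profile
#'
#' A gradient profile holds one gradient's ordered fractions: buoyant
#' densities, per-fraction DNA mass, and an amplicon count matrix
#' (fractions x OTUs). Densities must be strictly monotone along the
#' fraction order; decreasing (heavy-to-light collection) order is
#' accepted and internally reordered to increasing density.
#'
#' @param fractions Data frame with columns `fraction` (integer id),
#'   `density` (g/ml) and `dna_ng` (>= 0); optionally `n_c`.
#' @param counts Numeric matrix of non-negative read counts, one row per
#'   fraction, one named column per OTU.
#' @param sample_id Sample identifier.
#' @param isotope `"12C"` or `"13C"`.
#' @return Object of class `gradient_profile`.
#' @export
gradient_profile <- function(fractions, counts, sample_id = "sample",
                             isotope = c("12C", "13C")) {
  isotope <- match.arg(isotope)
  stopifnot(is.data.frame(fractions),
            all(c("fraction", "density", "dna_ng") %in% names(fractions)))
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have OTU column names")
  if (nrow(counts) != nrow(fractions))
    stop("counts rows must match fraction rows")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (any(fractions$dna_ng < 0)) stop("dna_ng must be non-negative")
  if (anyDuplicated(fractions$fraction))
    stop("duplicate fraction ids: ",
         paste(unique(fractions$fraction[duplicated(fractions$fraction)]),
               collapse = ", "))
  if (!is.null(fractions$n_c)) {
    disagree <- abs(refraction_to_density(fractions$n_c) -
                      fractions$density) > 1e-4
    if (any(disagree))
      stop("n_c and density disagree beyond 1e-4 g/ml in fraction(s) ",
           paste(fractions$fraction[disagree], collapse = ", "))
  }

  d <- fractions$density
  dd <- diff(d)
  if (all(dd < 0)) {              # heavy-to-light: reorder
    ord <- order(d)
    fractions <- fractions[ord, , drop = FALSE]
    counts <- counts[ord, , drop = FALSE]
  } else if (!all(dd > 0)) {
    off <- which(c(FALSE, dd <= 0) | c(dd <= 0, FALSE))
    stop("densities are not strictly monotone; offending fraction(s): ",
         paste(fractions$fraction[off], collapse = ", "))
  }
  rownames(counts) <- fractions$fraction
  n_dna <- sum(fractions$dna_ng > 0)
  if (n_dna < 5)
    warning("fewer than 5 fractions with dna_ng > 0; ",
            "profile is unsuitable for shift analysis")
  structure(list(sample_id = sample_id, isotope = isotope,
                 fractions = fractions, counts = counts),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("Gradient profile '%s' (%s): %d fractions, %d OTUs, %.3f-%.3f g/ml\n",
              x$sample_id, x$isotope, nrow(x$fractions), ncol(x$counts),
              min(x$fractions$density), max(x$fractions$density)))
  invisible(x)
}

#' OTU identifiers of a gradient profile
#' @param profile A [gradient_profile()].
#' @return Character vector of OTU ids.
#' @export
otu_ids <- function(profile) colnames(profile$counts)

#' Read a per-fraction gradient table
#'
#' Tab-separated, '.' decimal, '#' comment lines, one gradient per file.
#' Required columns: `fraction`, `dna_ng`, and at least one of `n_c` /
#' `density`; every remaining column is an OTU count column. When only
#' `n_c` is present, density is filled in via [refraction_to_density()].
#' Comment headers of the form `# key: value` supply `sample_id` and
#' `isotope` unless given explicitly.
#'
#' @param path Path to the TSV file.
#' @param sample_id,isotope Optional overrides of the file's metadata.
#' @param quiet Suppress the fraction/read-count log message.
#' @return A validated [gradient_profile()].
#' @export
read_gradient_table <- function(path, sample_id = NULL, isotope = NULL,
                                quiet = FALSE) {
  if (!file.exists(path)) stop("no such gradient table: ", path)
  meta <- .read_header_meta(path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("fraction", "dna_ng")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!("density" %in% names(tab)) && !("n_c" %in% names(tab)))
    stop("table must contain a density or n_c column")
  if (!("density" %in% names(tab)))
    tab$density <- refraction_to_density(tab$n_c)
  otu_cols <- setdiff(names(tab), .reserved_cols)
  if (!length(otu_cols)) stop("no OTU count columns found")
  counts <- as.matrix(tab[otu_cols])
  fr <- tab[intersect(.reserved_cols, names(tab))]
  sample_id <- sample_id %||% meta[["sample_id"]] %||% basename(path)
  isotope <- isotope %||% meta[["isotope"]] %||% "12C"
  prof <- gradient_profile(fr, counts, sample_id = sample_id,
                           isotope = isotope)
  if (!quiet)
    message(sprintf("read %s: %d fractions, %d OTUs, %d reads",
                    path, nrow(prof$fractions), ncol(prof$counts),
                    sum(prof$counts)))
  prof
}

.read_header_meta <- function(path) {
  lines <- readLines(path, n = 20L, warn = FALSE)
  lines <- grep("^#", lines, value = TRUE)
  m <- regmatches(lines, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(\\S+)", lines))
  m <- Filter(function(x) length(x) == 3, m)
  stats::setNames(lapply(m, `[[`, 3), vapply(m, `[[`, "", 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a gradient profile to a TSV file
#'
#' Inverse of [read_gradient_table()]; metadata goes into `# key: value`
#' comment headers.
#'
#' @param profile A [gradient_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gradient_table <- function(profile, path) {
  tab <- cbind(profile$fractions,
               as.data.frame(profile$counts, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sample_id: ", profile$sample_id),
               paste0("# isotope: ", profile$isotope)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a per-OTU shift results table
#'
#' Serializes the output of [compare_gradients()] with the fixed column
#' set `otu_id, taxonomy, ks_p_12C, ks_p_13C, wm_12C, wm_13C, delta_wm,
#' significant, eaf, ape`. Extra comment headers may carry run metadata.
#'
#' @param results Data frame of shift results (non-empty).
#' @param path Output path.
#' @param header Optional character vector written as '#' comment lines.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, header = character()) {
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("results must be a non-empty data frame")
  cols <- c("otu_id", "taxonomy", "ks_p_12C", "ks_p_13C", "wm_12C",
            "wm_13C", "delta_wm", "significant", "eaf", "ape")
  if (!("taxonomy" %in% names(results))) results$taxonomy <- NA_character_
  miss <- setdiff(cols, names(results))
  if (length(miss))
    stop("results missing column(s): ", paste(miss, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(results[cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a shift results table written by [write_results_table()]
#' @param path Path to the results TSV.
#' @return Data frame of shift results.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
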