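# Chi-angle nomenclature and hierarchical recovery scoring: a model
# conformation recovers a reference only as deep as every preceding chi
# matches, so depth-d percentages are non-increasing in d.

.canonical_mpt <- c(m = -60, p = 60, t = 180)

# smallest absolute circular difference between angles in degrees
.circ_diff <- function(a, b) {
  abs(wrap_angle(a - b))
}

#' Classify a torsion into the m/p/t nomenclature
#'
#' Canonical values are m = -60, p = +60 and t = 180 degrees. The nearest
#' canonical value by circular distance wins when it lies within
#' `window` (boundary inclusive); otherwise the angle is an `"outlier"`.
#'
#' @param angle torsion(s) in degrees (any real value; periodicity is
#'   respected).
#' @param window classification half-width in degrees.
#' @return character vector over `{"m", "p", "t", "outlier"}`.
#' @export
classify_chi <- function(angle, window = 30) {
  stopifnot(is.numeric(angle), all(is.finite(angle)))
  vapply(angle, function(a) {
    d <- .circ_diff(a, .canonical_mpt)
    k <- which.min(d)
    if (d[k] <= window) names(.canonical_mpt)[k] else "outlier"
  }, character(1L))
}

#' Deepest hierarchical chi match against reference conformations
#'
#' Finds the largest depth `d` such that chi1..chi_d of the model all lie
#' within `tolerance` (circular, boundary inclusive) of the corresponding
#' angles of a single reference. A reference's unresolved angles (`NA`)
#' terminate its usable depth; the model matches if it matches any one
#' reference.
#'
#' @param model numeric vector of up to 5 model torsions in degrees; `NA`
#'   entries are rejected (a built conformer always resolves its torsions).
#' @param references a list of reference chi vectors (each up to length 5,
#'   `NA` marking crystallographically unresolved angles), or a single
#'   numeric vector.
#' @param tolerance per-angle match tolerance in degrees.
#' @return integer depth in `0..5`.
#' @export
match_conformer <- function(model, references, tolerance = 30) {
  model <- as.numeric(model)
  if (length(model) < 1L || length(model) > 5L) {
    stop("model chi vector must have 1 to 5 entries", call. = FALSE)
  }
  if (anyNA(model)) {
    stop("model chi vector contains unresolved (NA) angles", call. = FALSE)
  }
  if (is.numeric(references)) references <- list(references)
  if (length(references) < 1L) stop("at least one reference is required", call. = FALSE)
  best <- 0L
  for (ref in references) {
    ref <- as.numeric(ref)
    depth <- 0L
    for (k in seq_len(min(length(model), length(ref)))) {
      if (is.na(ref[k])) break
      if (.circ_diff(model[k], ref[k]) > tolerance) break
      depth <- k
    }
    if (depth > best) best <- depth
  }
  best
}

#' Hierarchical chi-recovery percentages over a model set
#'
#' For each depth d in 1..5 reports the percentage of models whose match
#' depth (against any reference) is at least d. Because an angle only
#' counts when all preceding angles match, the report is non-increasing
#' with depth.
#'
#' @param models a list of model chi vectors, or a matrix with one row per
#'   model.
#' @param references list of reference chi vectors (NA = unresolved).
#' @param tolerance per-angle tolerance in degrees.
#' @return an object of class `"recovery_report"`: numeric vector of 5
#'   percentages named chi1..chi5, with attribute `n_models`.
#' @export
recovery_percentages <- function(models, references, tolerance = 30) {
  if (is.matrix(models)) models <- asplit(models, 1L)
  if (!is.list(models) || length(models) < 1L) {
    stop("at least one model is required", call. = FALSE)
  }
  depths <- vapply(models, match_conformer, integer(1L),
                   references = references, tolerance = tolerance)
  pct <- vapply(1:5, function(d) 100 * mean(depths >= d), numeric(1L))
  structure(stats::setNames(pct, paste0("chi", 1:5)),
            n_models = length(models), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Chi recovery over %d models (%% with all angles up to depth correct):\n",
              attr(x, "n_models")))
  print(round(unclass(x), 1))
  invisible(x)
}

#' Read a chi-angle table
#'
#' Tab-separated columns `label`, `chi1`..`chi5`; `NA` marks unresolved
#' angles. Lines starting with `#` are ignored.
#'
#' @param path input path.
#' @return named list of chi vectors (length 5, `NA` allowed).
#' @export
read_chi_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", check.names = FALSE)
  need <- c("label", paste0("chi", 1:5))
  if (!all(need %in% names(df))) {
    stop("chi table needs columns label, chi1..chi5: ", path, call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    as.numeric(df[i, paste0("chi", 1:5)])
  })
  names(out) <- as.character(df$label)
  out
}

#' Write a chi-angle table
#'
#' @param chis named list of chi vectors (length up to 5; padded with NA).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chi_table <- function(chis, path) {
  rows <- lapply(chis, function(v) {
    v <- as.numeric(v)
    length(v) <- 5L
    v
  })
  df <- cbind(data.frame(label = names(chis) %||% seq_along(chis)),
              stats::setNames(as.data.frame(do.call(rbind, rows)),
                              paste0("chi", 1:5)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
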