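# Wild-type vs mutant RMSF differencing with epitope annotation.
#
# Residues with RMSF increments or decrements of magnitude >= 0.7 Angstrom
# are flagged (inclusive threshold); residues with wild-type RMSF >= 2.5
# Angstrom are marked high-flexibility.  The shipped epitope annotation is
# the Discotope-predicted conformational epitope set of Mus m 1.0102.

#' Wild-type vs mutant per-residue RMSF differences
#'
#' One row per residue with `delta = rmsf_mut - rmsf_wt` and a flag:
#' `increased` when `delta >= threshold`, `decreased` when
#' `delta <= -threshold`, else `unchanged` (thresholds inclusive).  The
#' mutated position is matched by residue number even though its name
#' differs; a `res_name_mut` column records the mutant identity.
#'
#' @param wt,mut [rmsf_profile()] results over identical residue keys.
#' @param threshold flag threshold, Angstrom (default 0.7).
#' @param high_flex wild-type RMSF level marking highly flexible residues,
#'   Angstrom (default 2.5).
#' @return object of class `flex_delta` (a data.frame).
#' @export
delta_rmsf <- function(wt, mut, threshold = 0.7, high_flex = 2.5) {
  stopifnot(inherits(wt, "flex_profile"), inherits(mut, "flex_profile"))
  if (threshold <= 0 || high_flex <= 0) stop("thresholds must be > 0")
  kw <- paste(wt$chain, wt$res_seq)
  km <- paste(mut$chain, mut$res_seq)
  if (length(kw) != length(km) || !all(kw == km)) {
    off <- union(setdiff(kw, km), setdiff(km, kw))
    stop("residue keys differ between profiles: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  out <- data.frame(chain = wt$chain, res_seq = wt$res_seq,
                    res_name = wt$res_name, res_name_mut = mut$res_name,
                    rmsf_wt = wt$rmsf, rmsf_mut = mut$rmsf,
                    delta = mut$rmsf - wt$rmsf,
                    stringsAsFactors = FALSE)
  out$flag <- ifelse(out$delta >= threshold, "increased",
                     ifelse(out$delta <= -threshold, "decreased",
                            "unchanged"))
  out$high_flex_wt <- out$rmsf_wt >= high_flex
  out$epitope <- "none"
  attr(out, "threshold") <- threshold
  attr(out, "high_flex") <- high_flex
  class(out) <- c("flex_delta", "data.frame")
  out
}

#' @export
print.flex_delta <- function(x, ...) {
  cat("flex_delta:", nrow(x), "residues;",
      sum(x$flag == "increased"), "increased,",
      sum(x$flag == "decreased"), "decreased (threshold",
      attr(x, "threshold"), "A)\n")
  flagged <- x[x$flag != "unchanged", , drop = FALSE]
  if (nrow(flagged)) print.data.frame(flagged, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.flex_delta <- function(x, ...) {
  graphics::plot(x$res_seq, x$delta, type = "h",
                 xlab = "Residue", ylab = expression(Delta * "RMSF (Å)"),
                 col = ifelse(x$flag == "increased", "red3",
                              ifelse(x$flag == "decreased", "green4",
                                     "grey60")), ...)
  graphics::abline(h = c(-1, 1) * attr(x, "threshold"), lty = 2)
  invisible(x)
}

#' Conformational epitope annotation of Mus m 1.0102
#'
#' The Discotope-predicted epitope residue sets: epitope I (Glu1, Gly7,
#' Arg8, Asn9, Asn11, Glu13), epitope II (Glu30, Asp34, Asn35, Asp61) and
#' epitope III (Asp110, Gly111, Glu112).
#'
#' @param chain chain identifier the numbering refers to.
#' @return data.frame with `chain`, `res_seq`, `res_name`, `epitope`.
#' @export
default_epitopes <- function(chain = "A") {
  data.frame(
    chain = chain,
    res_seq = c(1, 7, 8, 9, 11, 13, 30, 34, 35, 61, 110, 111, 112),
    res_name = c("GLU", "GLY", "ARG", "ASN", "ASN", "GLU",
                 "GLU", "ASP", "ASN", "ASP", "ASP", "GLY", "GLU"),
    epitope = c(rep("I", 6), rep("II", 4), rep("III", 3)),
    stringsAsFactors = FALSE)
}

#' Annotate RMSF differences with conformational epitope labels
#'
#' Attaches epitope labels to a [delta_rmsf()] table and summarises, per
#' epitope, how many residues gained or lost flexibility.
#'
#' @param deltas a `flex_delta` table.
#' @param annotation data.frame with `chain`, `res_seq`, `epitope` (default
#'   [default_epitopes()]).  Annotation rows referring to residues absent
#'   from the profile raise a warning, not an error.
#' @return the annotated `flex_delta`, with a `summary` attribute counting
#'   `increased` / `decreased` / `unchanged` per epitope.
#' @export
annotate_epitopes <- function(deltas, annotation = default_epitopes()) {
  stopifnot(inherits(deltas, "flex_delta"))
  if (length(unique(annotation$epitope[annotation$epitope != "none"])) !=
      length(unique(annotation$epitope)) &&
      anyDuplicated(paste(annotation$chain, annotation$res_seq)))
    stop("epitope labels must be disjoint over residues")
  key_d <- paste(deltas$chain, deltas$res_seq)
  key_a <- paste(annotation$chain, annotation$res_seq)
  absent <- !(key_a %in% key_d)
  if (any(absent))
    warning("annotation refers to residues absent from the profile: ",
            paste(key_a[absent], collapse = ", "))
  hit <- match(key_d, key_a)
  deltas$epitope <- ifelse(is.na(hit), "none", annotation$epitope[hit])
  labs <- setdiff(unique(annotation$epitope), "none")
  summ <- do.call(rbind, lapply(labs, function(l) {
    sub <- deltas[deltas$epitope == l, , drop = FALSE]
    data.frame(epitope = l, n = nrow(sub),
               increased = sum(sub$flag == "increased"),
               decreased = sum(sub$flag == "decreased"),
               unchanged = sum(sub$flag == "unchanged"),
               stringsAsFactors = FALSE)
  }))
  attr(deltas, "summary") <- summ
  deltas
}
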