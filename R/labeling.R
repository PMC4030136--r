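#' Label single trials with template maps
#'
#' Assigns each map to the template with the highest absolute spatial
#' correlation (ties broken by the lowest template index) and records the
#' correlation, the map GFP, and the GEV contribution
#' \eqn{GFP^2 C^2} (normalized later by the condition's total \eqn{GFP^2}).
#'
#' @param maps trials x channels matrix or an \code{ms_peakmaps}.
#' @param templates channels x k template matrix.
#' @param polarity_invariant assign by |C| (default TRUE).
#' @return object of class \code{ms_labeling}: a data.frame with columns
#'   trial, subject, condition, label, C (signed correlation to the chosen
#'   template), abs_C, gfp, gev_contrib, plus the template matrix as an
#'   attribute.
#' @export
label_trials <- function(maps, templates, polarity_invariant = TRUE) {
  pm <- if (inherits(maps, "ms_peakmaps")) maps else NULL
  X <- as_map_matrix(maps)
  if (ncol(X) != nrow(templates))
    stop("maps and templates disagree on channel count")
  if (ncol(templates) < 1) stop("templates must be nonempty")
  Xc <- X - rowMeans(X)
  nX <- sqrt(rowSums(Xc^2))
  if (any(nX < 1e-15)) stop("zero-norm map: correlation undefined")
  Tc <- sweep(templates, 2, colMeans(templates))
  nT <- sqrt(colSums(Tc^2))
  if (any(nT < 1e-15)) stop("zero-norm template")
  C <- (Xc %*% Tc) / outer(nX, nT)               # n x k signed correlations
  score <- if (polarity_invariant) abs(C) else C
  lab <- max.col(score, ties.method = "first")
  csel <- C[cbind(seq_len(nrow(X)), lab)]
  g <- gfp(t(X))
  df <- data.frame(
    trial = if (is.null(pm)) seq_len(nrow(X)) else pm$info$trial,
    subject = if (is.null(pm)) "S01" else pm$info$subject,
    condition = if (is.null(pm)) NA_character_ else pm$info$condition,
    label = lab, C = csel, abs_C = abs(csel), gfp = g,
    gev_contrib = g^2 * csel^2)
  structure(list(table = df, templates = templates,
                 correlations = C), class = "ms_labeling")
}

#' @export
print.ms_labeling <- function(x, ...) {
  cat("<ms_labeling> ", nrow(x$table), " trials labeled with ",
      ncol(x$templates), " templates\n", sep = "")
  print(table(label = x$table$label, condition = x$table$condition))
  invisible(x)
}

#' GEV per subject, template and condition
#'
#' \deqn{GEV(k, cond) = \sum_{t \in cond, L_t = k} GFP_t^2 C_t^2 /
#'   \sum_{t \in cond} GFP_t^2,} computed within each subject so that
#' condition GEVs are comparable across subjects with different trial
#' counts.
#'
#' @param labeling an \code{ms_labeling}.
#' @param conditions optional override of the per-trial condition labels.
#' @return data.frame: subject, template, condition, gev.
#' @export
gev_by_map_condition <- function(labeling, conditions = NULL) {
  df <- labeling$table
  if (!is.null(conditions)) df$condition <- conditions
  if (anyNA(df$condition)) stop("condition labels are required")
  k <- ncol(labeling$templates)
  out <- expand.grid(subject = unique(df$subject), template = seq_len(k),
                     condition = unique(df$condition),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$gev <- mapply(function(s, tpl, cond) {
    sel <- df$subject == s & df$condition == cond
    if (!any(sel)) stop("no trials for subject ", s, " in condition ", cond)
    denom <- sum(df$gfp[sel]^2)
    sum(df$gev_contrib[sel & df$label == tpl]) / denom
  }, out$subject, out$template, out$condition)
  out
}

#' Condition contrast of a template's GEV across subjects
#'
#' Paired two-tailed t test across subjects on GEV(template, CA) versus
#' GEV(template, CU); df = n_subjects - 1. Positive t means higher GEV in
#' the CA condition.
#'
#' @param gev_table output of \code{\link{gev_by_map_condition}}.
#' @param template_index template to test.
#' @return \code{ms_test} with an added \code{template} field.
#' @export
compare_gev <- function(gev_table, template_index) {
  sub <- gev_table[gev_table$template == template_index, ]
  wide <- merge(sub[sub$condition == "CA", c("subject", "gev")],
                sub[sub$condition == "CU", c("subject", "gev")],
                by = "subject", suffixes = c("_CA", "_CU"))
  if (nrow(wide) < 2) stop("need >= 2 subjects with both conditions")
  res <- paired_t(wide$gev_CA, wide$gev_CU)
  res$template <- template_index
  res
}
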