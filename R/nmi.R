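#' Shannon entropy of a label vector
#'
#' Empirical-frequency entropy in nats, \eqn{H = -\sum_c \hat p_c \ln \hat p_c}.
#' Natural logarithms are used throughout the NMI metrics; the normalization
#' makes the base cancel, so values are identical in bits or nats.
#'
#' @param x Vector of categorical labels (any atomic type).
#' @return Non-negative entropy in nats.
#' @export
label_entropy <- function(x) {
  if (length(x) == 0L) abort("cannot take the entropy of an empty label vector")
  if (anyNA(x)) abort("labels must not contain NA; filter first")
  p <- tabulate(as.integer(factor(x)))
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Normalized mutual information between two labelings
#'
#' \eqn{\mathrm{NMI}(X,Y) = \mathrm{MI}(X,Y) / ((H(X)+H(Y))/2)} with mutual
#' information and entropies computed from empirical frequencies of the joint
#' contingency table. If exactly one vector is constant the score is 0 (its
#' entropy is zero, so it carries no information); if both are constant the
#' partitions are trivially identical and the score is 1.
#'
#' @param x,y Equal-length label vectors.
#' @return A value in `[0, 1]`.
#' @export
nmi <- function(x, y) {
  if (length(x) != length(y)) {
    abort(sprintf("label vectors differ in length (%d vs %d)", length(x), length(y)))
  }
  if (length(x) < 2L) abort("need at least 2 samples")
  if (anyNA(x) || anyNA(y)) abort("labels must not contain NA; filter first")
  hx <- label_entropy(x)
  hy <- label_entropy(y)
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  mi <- max(mi, 0) # guard tiny negative rounding
  min(mi / ((hx + hy) / 2), 1)
}

#' Phenotype NMI (pNMI)
#'
#' NMI between a cluster assignment and known phenotype labels — the quantity
#' to maximize. Samples with missing phenotype are dropped pairwise before
#' the computation.
#'
#' @param clusters Cluster labels, one per sample.
#' @param phenotypes Phenotype labels, `NA` allowed.
#' @return pNMI in `[0, 1]`.
#' @export
pnmi <- function(clusters, phenotypes) {
  if (length(clusters) != length(phenotypes)) abort("length mismatch")
  keep <- !is.na(phenotypes)
  if (!any(keep)) abort("all phenotypes missing: pNMI undefined")
  nmi(clusters[keep], phenotypes[keep])
}

#' Experiment NMI (eNMI)
#'
#' NMI between a cluster assignment and study/experiment identifiers — the
#' quantity to minimize: study-driven clustering is technical, not biological.
#' All samples are used by default; set `annotated_only = TRUE` to restrict
#' to samples with a phenotype label (pass it in `phenotypes`).
#'
#' @param clusters Cluster labels.
#' @param studies Study identifiers.
#' @param annotated_only Restrict to phenotype-annotated samples.
#' @param phenotypes Needed when `annotated_only = TRUE`.
#' @return eNMI in `[0, 1]`.
#' @export
enmi <- function(clusters, studies, annotated_only = FALSE, phenotypes = NULL) {
  if (length(clusters) != length(studies)) abort("length mismatch")
  if (annotated_only) {
    if (is.null(phenotypes)) abort("`phenotypes` required when annotated_only = TRUE")
    keep <- !is.na(phenotypes)
    clusters <- clusters[keep]
    studies <- studies[keep]
  }
  if (anyNA(studies)) abort("study ids must not be missing")
  nmi(clusters, studies)
}

#' Combined NMI (cNMI)
#'
#' \eqn{\mathrm{cNMI} = (\mathrm{pNMI} + (1 - \mathrm{eNMI})) / 2}: high when
#' clustering separates phenotypes and ignores study of origin.
#'
#' @param pnmi_value,enmi_value Values in `[0, 1]`.
#' @return cNMI in `[0, 1]`.
#' @export
cnmi <- function(pnmi_value, enmi_value) {
  if (any(pnmi_value < 0 | pnmi_value > 1) || any(enmi_value < 0 | enmi_value > 1)) {
    abort("pNMI and eNMI must lie in [0, 1]")
  }
  (pnmi_value + (1 - enmi_value)) / 2
}
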