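#' Effect-weight table for PRS scoring
#'
#' Validates a per-SNP weight table: SNP identifier, effect allele, effect
#' size (log odds ratio from an independent GWAS) and, optionally, the
#' effect-allele frequency.
#'
#' @param snp_id Character vector of SNP identifiers, unique.
#' @param effect_allele Character vector of single-nucleotide codes; dosages
#'   count copies of this allele.
#' @param beta Numeric vector of log odds ratios, finite.
#' @param maf Optional numeric vector of effect-allele frequencies in (0, 1).
#' @return A `data.frame` of class `effect_weights`.
#' @export
effect_weights <- function(snp_id, effect_allele, beta, maf = NULL) {
  snp_id <- as.character(snp_id)
  effect_allele <- toupper(as.character(effect_allele))
  stopifnot(length(effect_allele) == length(snp_id),
            length(beta) == length(snp_id))
  if (anyDuplicated(snp_id))
    stop("duplicate snp_id in weights: ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  if (!is.numeric(beta) || any(!is.finite(beta)))
    stop("beta must be finite numeric log odds ratios")
  if (!all(effect_allele %in% c("A", "C", "G", "T")))
    stop("effect_allele must be a single nucleotide code (A/C/G/T)")
  w <- data.frame(snp_id = snp_id, effect_allele = effect_allele,
                  beta = as.numeric(beta), stringsAsFactors = FALSE)
  if (!is.null(maf)) {
    stopifnot(length(maf) == length(snp_id))
    if (any(!is.na(maf) & (maf <= 0 | maf >= 1)))
      stop("allele frequencies must lie in (0, 1)")
    w$maf <- as.numeric(maf)
  }
  class(w) <- c("effect_weights", "data.frame")
  w
}

.check_weights <- function(weights) {
  if (is.data.frame(weights) && !inherits(weights, "effect_weights"))
    weights <- effect_weights(weights$snp_id, weights$effect_allele,
                              weights$beta, weights$maf)
  if (!inherits(weights, "effect_weights"))
    stop("weights must be an 'effect_weights' table (see effect_weights())")
  weights
}

.check_genotypes <- function(genotypes) {
  if (is.data.frame(genotypes)) genotypes <- as.matrix(genotypes)
  if (!is.matrix(genotypes) || !is.numeric(genotypes))
    stop("genotypes must be a numeric matrix (individuals x SNPs) of allele dosages")
  if (is.null(colnames(genotypes)))
    stop("genotype matrix must carry SNP ids as column names")
  bad <- !is.na(genotypes) & !(genotypes %in% c(0, 1, 2))
  if (any(bad))
    stop("invalid dosages (must be 0, 1 or 2): first offender value ",
         format(genotypes[which(bad)[1]]))
  genotypes
}

#' Per-individual score set
#'
#' Holds the PRS values of a sample, with optional case/control status.
#'
#' @param values Numeric vector of PRS values.
#' @param status Optional integer vector, 1 = case, 0 = control, aligned
#'   with `values`.
#' @param n_snps Number of SNPs that contributed to each score (recorded for
#'   provenance; `NA` when scores come from summary-level simulation).
#' @param ids Optional individual identifiers.
#' @return An object of class `score_set`.
#' @export
score_set <- function(values, status = NULL, n_snps = NA_integer_, ids = NULL) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (!is.null(status)) {
    status <- as.integer(status)
    stopifnot(length(status) == length(values), all(status %in% c(0L, 1L)))
  }
  if (!is.null(ids)) stopifnot(length(ids) == length(values))
  structure(list(values = as.numeric(values), status = status,
                 n_individuals = length(values),
                 n_snps = as.integer(n_snps), ids = ids),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("PRS score set: %d individuals", x$n_individuals))
  if (!is.na(x$n_snps)) cat(sprintf(", %d SNPs", x$n_snps))
  if (!is.null(x$status))
    cat(sprintf(" (%d cases / %d controls)", sum(x$status == 1L), sum(x$status == 0L)))
  cat("\n")
  invisible(x)
}

#' Compute polygenic risk scores from a dosage matrix and effect weights
#'
#' For individual \eqn{j}, the score is the average weighted dosage
#' \deqn{PRS_j = \frac{1}{N_{snps}} \sum_i g_{ij} \beta_i}
#' where \eqn{g_{ij} \in \{0,1,2\}} counts copies of the effect allele and
#' \eqn{\beta_i} is the SNP's log odds ratio. Note the \eqn{1/N_{snps}}
#' divisor: scores are averages, not sums, so their scale shrinks with the
#' number of SNPs. Downstream calibration is unaffected because it only uses
#' moments computed on the same scale.
#'
#' Individuals with a missing dosage at any weighted SNP are dropped with a
#' warning rather than imputed.
#'
#' @param genotypes Numeric matrix, individuals as rows, SNPs as columns
#'   (column names are SNP ids); entries are effect-allele dosages 0/1/2,
#'   `NA` for missing.
#' @param weights An [effect_weights()] table covering every SNP column.
#' @return A [score_set()] with `n_snps` recorded.
#' @export
compute_prs <- function(genotypes, weights) {
  genotypes <- .check_genotypes(genotypes)
  weights <- .check_weights(weights)
  snps <- colnames(genotypes)
  if (length(snps) == 0L) stop("empty SNP set: genotype matrix has no columns")
  missing_w <- setdiff(snps, weights$snp_id)
  if (length(missing_w))
    stop("no effect weight for SNP(s): ", paste(missing_w, collapse = ", "))
  beta <- weights$beta[match(snps, weights$snp_id)]
  keep <- !apply(is.na(genotypes), 1L, any)
  if (!all(keep)) {
    warning(sum(!keep), " individual(s) dropped: missing dosage at a weighted SNP")
    genotypes <- genotypes[keep, , drop = FALSE]
  }
  if (nrow(genotypes) == 0L) stop("no individuals left after dropping missing genotypes")
  prs <- as.numeric(genotypes %*% beta) / length(snps)
  score_set(prs, n_snps = length(snps), ids = rownames(genotypes))
}

#' Sample moments of a score set
#'
#' Mean and variance with the \eqn{1/N_{ind}} divisor (population variance,
#' not the `var()` default \eqn{1/(N-1)}):
#' \deqn{m = \frac{1}{N}\sum_j PRS_j, \qquad
#'       \mathrm{var} = \frac{1}{N}\sum_j (PRS_j - m)^2.}
#' For the sample sizes this framework targets (thousands), the two
#' conventions are numerically indistinguishable; the `1/N` divisor is kept
#' for consistency with the calibration formulas.
#'
#' @param scores A [score_set()]; when it carries case/control status,
#'   `label = "cases"` or `"noncases"` restricts to that subgroup.
#' @param label Which group the moments describe: `"population"` (all
#'   values), `"cases"`, or `"noncases"`.
#' @return A [group_moments()] object.
#' @export
sample_moments <- function(scores, label = c("population", "cases", "noncases")) {
  label <- match.arg(label)
  if (!inherits(scores, "score_set")) stop("scores must be a 'score_set'")
  v <- scores$values
  if (label != "population") {
    if (is.null(scores$status))
      stop("score set carries no case/control status; cannot take ", label, " moments")
    v <- v[scores$status == if (label == "cases") 1L else 0L]
  }
  n <- length(v)
  if (n < 2L) stop("at least 2 values are needed to compute moments (got ", n, ")")
  m <- sum(v) / n
  s2 <- sum((v - m)^2) / n
  group_moments(m, s2, label)
}
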