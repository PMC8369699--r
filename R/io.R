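#' Read an effect-weight table
#'
#' Tab-separated file with header `snp_id  effect_allele  beta  maf` (the
#' `maf` column is optional). Malformed effect sizes are reported with
#' their line number; duplicate SNP ids are an error.
#'
#' @param path Path to the weights file.
#' @return An [effect_weights()] table.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  need <- c("snp_id", "effect_allele", "beta")
  if (!all(need %in% names(raw)))
    stop("weights file must have columns ", paste(need, collapse = ", "),
         " (tab-separated with header)")
  beta <- suppressWarnings(as.numeric(raw$beta))
  bad <- which(is.na(beta))
  if (length(bad))
    stop("malformed beta '", raw$beta[bad[1]], "' at line ", bad[1] + 1L,
         " of ", path)
  maf <- NULL
  if ("maf" %in% names(raw) && any(nzchar(raw$maf))) {
    maf <- suppressWarnings(as.numeric(raw$maf))
    bad <- which(is.na(maf) & nzchar(raw$maf))
    if (length(bad))
      stop("malformed maf '", raw$maf[bad[1]], "' at line ", bad[1] + 1L,
           " of ", path)
  }
  effect_weights(raw$snp_id, raw$effect_allele, beta, maf)
}

#' Write an effect-weight table
#'
#' @param weights An [effect_weights()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  weights <- .check_weights(weights)
  df <- as.data.frame(weights)
  df$beta <- sprintf("%.10g", df$beta)
  if (!is.null(df$maf)) df$maf <- sprintf("%.10g", df$maf)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype dosage matrix
#'
#' Two supported sources:
#' \describe{
#'   \item{`"tsv"`}{tab-separated, individuals as rows; first column is the
#'     individual id, remaining columns are dosages 0/1/2 with SNP ids in
#'     the header. Dosages are assumed to count the effect allele already.}
#'   \item{`"vcf"`}{diploid GT fields; dosage counts ALT alleles and is
#'     flipped to `2 - g` when the weight's effect allele is the REF
#'     allele. Records are matched to weights by SNP id, never position.}
#' }
#' In both cases every SNP in `weights` must be present; individuals with a
#' missing dosage at any weighted SNP are dropped (counted in a warning).
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param weights [effect_weights()]; defines the SNP set and effect
#'   alleles.
#' @return Numeric matrix (individuals x SNPs) of effect-allele dosages,
#'   restricted and ordered to the weighted SNPs.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), weights) {
  format <- match.arg(format)
  weights <- .check_weights(weights)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  G <- if (format == "tsv") .read_genotypes_tsv(path) else .read_genotypes_vcf(path, weights)
  missing_snps <- setdiff(weights$snp_id, colnames(G))
  if (length(missing_snps))
    stop("weighted SNP(s) absent from genotype input: ",
         paste(missing_snps, collapse = ", "))
  G <- G[, weights$snp_id, drop = FALSE]
  G <- .check_genotypes(G)
  drop <- apply(is.na(G), 1L, any)
  if (any(drop)) {
    warning(sum(drop), " individual(s) dropped: missing genotype at a weighted SNP")
    G <- G[!drop, , drop = FALSE]
  }
  if (nrow(G) == 0L) stop("no individuals with complete genotypes at the weighted SNPs")
  G
}

.read_genotypes_tsv <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (ncol(raw) < 2L) stop("genotype TSV needs an id column plus at least one SNP column")
  ids <- as.character(raw[[1]])
  G <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(G) <- "numeric"
  rownames(G) <- ids
  G
}

.read_genotypes_vcf <- function(path, weights) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF genotypes requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  gt <- vcfR::extract.gt(v, element = "GT")
  # ALT-allele dosage from diploid GT, any separator; missing -> NA
  alt_dosage <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2L || any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  D <- apply(gt, c(1, 2), alt_dosage)
  keep <- ids %in% weights$snp_id
  D <- D[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (nrow(D) == 0L) stop("no overlap between VCF records and weighted SNPs")
  w <- weights[match(fix[, "ID"], weights$snp_id), ]
  for (r in seq_len(nrow(D))) {
    ea <- w$effect_allele[r]
    if (ea == toupper(fix[r, "REF"])) {
      D[r, ] <- 2 - D[r, ]
    } else if (ea != toupper(fix[r, "ALT"])) {
      stop("effect allele ", ea, " for SNP ", fix[r, "ID"],
           " matches neither REF (", fix[r, "REF"], ") nor ALT (",
           fix[r, "ALT"], ")")
    }
  }
  t(D)  # individuals x SNPs
}

#' Read a flat summary-parameter configuration
#'
#' Flat key-value file (YAML-compatible subset, no nesting) with keys `K`,
#' `m_cases`, `var_cases` and *either* (`m_noncases`, `var_noncases`) or
#' (`m_population`, `var_population`) — the latter for unscreened controls,
#' in which case non-case moments are inferred via
#' [infer_noncase_moments()]. Optional keys: `grid_lo`, `grid_hi`, `grid_n`,
#' `seed`.
#'
#' @param path Path to the config file.
#' @return A list of class `run_config` with fields `K`, `cases`,
#'   `noncases`, `population` ([group_moments()] objects; `noncases`
#'   inferred when only population moments were supplied), grid spec and
#'   seed.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be flat key-value pairs")
  num <- function(key) {
    x <- cfg[[key]]
    if (is.null(x)) return(NULL)
    x <- suppressWarnings(as.numeric(x))
    if (is.na(x)) stop("config key '", key, "' is not numeric")
    x
  }
  K <- num("K")
  if (is.null(K)) stop("config must set K")
  .check_prevalence(K)
  if (is.null(num("m_cases")) || is.null(num("var_cases")))
    stop("config must set m_cases and var_cases")
  cases <- group_moments(num("m_cases"), num("var_cases"), "cases")
  has_nc <- !is.null(num("m_noncases")) && !is.null(num("var_noncases"))
  has_pop <- !is.null(num("m_population")) && !is.null(num("var_population"))
  if (has_nc == has_pop)
    stop("config must set exactly one of (m_noncases, var_noncases) or ",
         "(m_population, var_population)")
  if (has_nc) {
    noncases <- group_moments(num("m_noncases"), num("var_noncases"), "noncases")
    population <- mixture_moments(cases, noncases, K)
  } else {
    population <- group_moments(num("m_population"), num("var_population"), "population")
    noncases <- infer_noncase_moments(population, cases, K)
  }
  structure(list(K = K, cases = cases, noncases = noncases,
                 population = population,
                 grid_lo = if (is.null(num("grid_lo"))) -4 else num("grid_lo"),
                 grid_hi = if (is.null(num("grid_hi"))) 4 else num("grid_hi"),
                 grid_n = if (is.null(num("grid_n"))) 161L else as.integer(num("grid_n")),
                 seed = if (is.null(num("seed"))) 1L else as.integer(num("seed")),
                 source = path),
            class = "run_config")
}

#' Write a tabulated probability curve
#'
#' Tab-separated `x_st  probability  raw_probability` with a comment header
#' recording the curve coefficients, the prevalence and the source moments.
#' Probabilities are written to 6 decimal places, grid values to 10
#' significant digits.
#'
#' @param ct A `curve_table` from [probability_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_table <- function(ct, path) {
  if (!inherits(ct, "curve_table")) stop("ct must be a 'curve_table'")
  pop <- attr(ct, "population")
  hdr <- c(
    sprintf("# alpha=%.10g beta=%.10g K=%.10g", attr(ct, "alpha"),
            attr(ct, "beta"), attr(ct, "K")),
    sprintf("# m_p=%.10g var_p=%.10g", pop$mean, pop$variance)
  )
  cols <- c("x_st", "probability",
            if ("raw_probability" %in% names(ct)) "raw_probability")
  lines <- c(hdr, paste(cols, collapse = "\t"))
  fmt <- function(v, p) if (p) sprintf("%.6f", v) else sprintf("%.10g", v)
  body <- do.call(paste, c(lapply(cols, function(cn) fmt(ct[[cn]], cn != "x_st")),
                           sep = "\t"))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a tabulated probability curve
#'
#' @param path Path written by [write_curve_table()].
#' @return A `curve_table` data frame (attributes `alpha`, `beta`, `K`
#'   restored from the comment header).
#' @export
read_curve_table <- function(path) {
  if (!file.exists(path)) stop("curve table not found: ", path)
  all_lines <- readLines(path)
  hdr <- all_lines[startsWith(all_lines, "#")]
  ct <- utils::read.delim(text = all_lines[!startsWith(all_lines, "#")],
                          sep = "\t")
  take <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-+0-9.eE]+"), hdr))
    m <- m[nzchar(m)]
    if (!length(m)) return(NA_real_)
    as.numeric(sub(paste0(key, "="), "", m[1]))
  }
  attr(ct, "alpha") <- take("alpha")
  attr(ct, "beta") <- take("beta")
  attr(ct, "K") <- take("K")
  class(ct) <- c("curve_table", "data.frame")
  ct
}

#' Probability report for a set of PRS values
#'
#' The orchestration entry point: given summary parameters, evaluates the
#' disease probability for each supplied PRS value, optionally combining
#' rare-variant intrinsic probabilities and/or selecting a
#' genotype-stratified curve for a high-effect common variant.
#'
#' @param config A `run_config` (see [read_run_config()]), or any list with
#'   fields `K`, `cases`, `noncases`, `population`.
#' @param prs Numeric vector of raw PRS values on the scale of the config
#'   moments.
#' @param rare Optional list of [rare_variant()] objects carried by the
#'   individual(s); their combined intrinsic probability is folded in via
#'   [combined_probability()].
#' @param variant Optional list with fields `f` (risk-allele frequency),
#'   `odds_ratio` and `genotype` (0, 1 or 2): selects the corresponding
#'   genotype-stratified curve (the config moments must then describe a PRS
#'   excluding the variant's region).
#' @return A `data.frame` of class `probability_report` with columns `prs`,
#'   `x_st`, `probability_prs`, `probability`; provenance is stored in
#'   attributes (`curve`, `K_used`, `p_rare`).
#' @export
run_probability <- function(config, prs, rare = NULL, variant = NULL) {
  stopifnot(is.numeric(prs), all(is.finite(prs)))
  K <- config$K
  cases <- .check_moments(config$cases, "config$cases")
  noncases <- .check_moments(config$noncases, "config$noncases")
  population <- .check_moments(config$population, "config$population")
  if (is.null(variant)) {
    curve <- closed_form_coefficients(cases, noncases, K)
    K_used <- K
    stratum <- "all"
  } else {
    stopifnot(is.list(variant), !is.null(variant$f), !is.null(variant$odds_ratio),
              !is.null(variant$genotype), variant$genotype %in% 0:2)
    strata <- stratified_curves(cases, noncases, K, variant$f, variant$odds_ratio)
    stratum <- c("noncarrier", "heterozygote", "homozygote")[variant$genotype + 1L]
    curve <- strata[[stratum]]
    K_used <- curve$K
  }
  p_prs <- logistic_probability(curve, prs)
  p_rare <- NA_real_
  p <- p_prs
  if (!is.null(rare)) {
    p_rare <- combine_intrinsic(rare)
    p <- combined_probability(p_prs, p_rare)
  }
  out <- data.frame(prs = prs, x_st = standardize(prs, population),
                    probability_prs = p_prs, probability = p)
  attr(out, "curve") <- curve
  attr(out, "K_used") <- K_used
  attr(out, "stratum") <- stratum
  attr(out, "p_rare") <- p_rare
  class(out) <- c("probability_report", "data.frame")
  out
}
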