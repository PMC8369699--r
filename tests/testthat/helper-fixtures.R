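# Small in-code fixtures for IO tests.

demo_weights <- function() {
  effect_weights(
    snp_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "G", "T"),
    beta = c(0.2, -0.1, 0.4),
    maf = c(0.3, 0.2, 0.45)
  )
}

write_weights_file <- function(dir = tempdir(), lines = NULL) {
  path <- tempfile("weights", dir, ".tsv")
  if (is.null(lines))
    lines <- c("snp_id\teffect_allele\tbeta\tmaf",
               "rs1\tA\t0.2\t0.3",
               "rs2\tG\t-0.1\t0.2",
               "rs3\tT\t0.4\t0.45")
  writeLines(lines, path)
  path
}

write_genotype_tsv <- function(dir = tempdir(), body = NULL) {
  path <- tempfile("geno", dir, ".tsv")
  if (is.null(body))
    body <- c("id\trs1\trs2\trs3",
              "ind1\t0\t1\t2",
              "ind2\t2\t0\t1",
              "ind3\t1\t2\t0")
  writeLines(body, path)
  path
}

# Two-SNP, three-sample VCF. rs1: effect allele A is the REF -> dosages flip;
# rs2: effect allele G is the ALT -> dosages count ALT.
write_demo_vcf <- function(dir = tempdir()) {
  path <- tempfile("geno", dir, ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "2\t200\trs2\tT\tG\t.\tPASS\t.\tGT\t0|1\t1/1\t./."
  ), path)
  path
}

write_config_file <- function(dir = tempdir(), population = FALSE,
                              K = 0.1, m1 = 0.5, v1 = 1, m0 = 0, v0 = 1) {
  path <- tempfile("config", dir, ".yml")
  lines <- c(sprintf("K: %g", K),
             sprintf("m_cases: %g", m1),
             sprintf("var_cases: %g", v1))
  if (population) {
    pop <- mixture_moments(group_moments(m1, v1, "cases"),
                           group_moments(m0, v0, "noncases"), K)
    lines <- c(lines, sprintf("m_population: %.15g", pop$mean),
               sprintf("var_population: %.15g", pop$variance))
  } else {
    lines <- c(lines, sprintf("m_noncases: %g", m0),
               sprintf("var_noncases: %g", v0))
  }
  writeLines(lines, path)
  path
}
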