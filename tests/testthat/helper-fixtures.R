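# In-code builders for small test objects.

toy_pheno <- function(values, sugars = NULL, strains = NULL, branch = NULL) {
  if (is.null(strains)) strains <- paste0("s", seq_len(nrow(values)))
  if (is.null(sugars)) sugars <- paste0("sug", seq_len(ncol(values)))
  dimnames(values) <- list(strains, sugars)
  PhenotypeMatrix(values, branchOf = branch)
}

toy_states <- function(values, genes = NULL, strains = NULL) {
  if (is.null(strains)) strains <- paste0("s", seq_len(nrow(values)))
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(values)))
  dimnames(values) <- list(strains, genes)
  GeneStateMatrix(values)
}

# the melibiase worked example reconstructed from the prose counts:
# 29 strains with the gene intact (all melibiose positive), 12 pseudogene
# carriers of which 4 are positive and 8 negative
prose_melibiose_example <- function() {
  n <- 41
  strains <- paste0("m", seq_len(n))
  states <- matrix(c(rep("INTACT", 29), rep("PSEUDOGENE", 12)),
                   ncol = 1, dimnames = list(strains, "galA"))
  pheno <- matrix(c(rep(1L, 29), rep(1L, 4), rep(0L, 8)),
                  ncol = 1, dimnames = list(strains, "melibiose"))
  list(genes = GeneStateMatrix(states), phenotypes = PhenotypeMatrix(pheno))
}

# brute-force two-sided Fisher p from binomial coefficients (independent
# of dhyper), point-probability rule with the same 1e-7 tie tolerance
enum_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d; m <- a + b; n2 <- c + d; k <- a + c
  sup <- max(0, k - n2):min(k, m)
  pr <- choose(m, sup) * choose(n2, k - sup) / choose(n, k)
  pobs <- choose(m, a) * choose(n2, k - a) / choose(n, k)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# random gene-state matrix for property tests
random_states <- function(n_strains, genes, seed) {
  set.seed(seed)
  m <- matrix(sample(c("ABSENT", "PSEUDOGENE", "SINGULAR", "INTACT"),
                     n_strains * length(genes), replace = TRUE),
              nrow = n_strains,
              dimnames = list(paste0("s", seq_len(n_strains)), genes))
  GeneStateMatrix(m)
}
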