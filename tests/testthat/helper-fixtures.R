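# Tiny fixtures built in code; every helper takes a seed so tests stay
# deterministic.

tiny_counts <- function(vals = c(5, 9, 2, 7, 40, 35, 80, 60),
                        n_genes = 2, lib_groups = c("A", "A", "B", "B")) {
  m <- matrix(vals, nrow = n_genes, byrow = TRUE)
  cm <- count_matrix(m, paste0("g", seq_len(n_genes)),
                     paste0("lib", seq_along(lib_groups)))
  gm <- group_map(lib_groups, library_ids = cm$library_ids)
  list(counts = cm, groups = gm)
}

tiny_model <- function(fix, norm = NULL) {
  countHDP:::build_model(fix$counts, fix$groups, norm)
}

# Construct a posterior_samples object directly from a list of z matrices.
fake_samples <- function(z_list, group_names = c("A", "B"),
                         gene_ids = NULL) {
  n <- nrow(z_list[[1]])
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n))
  structure(list(z_samples = lapply(z_list, function(z) {
                   storage.mode(z) <- "integer"; z
                 }),
                 phi_samples = NULL, gene_ids = gene_ids,
                 group_names = group_names,
                 occupancy = integer(0), norm = NULL, config = NULL,
                 final_state = NULL),
            class = "posterior_samples")
}

# Reference NB log-pmf via dnbinom/dpois, used as the independent oracle.
ref_nb <- function(y, m, phi) {
  if (phi == 0) dpois(y, m, log = TRUE)
  else dnbinom(y, mu = m, size = 1 / phi, log = TRUE)
}
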