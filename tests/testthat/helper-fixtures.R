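# small in-code fixtures shared across test files

make_ann <- function(n, panel = "P1") {
  data.frame(reaction_id = sprintf("r%02d", seq_len(n)),
             panel = panel, condition = sprintf("c%02d", seq_len(n)),
             group = "none", bio_rep = 1L, tech_rep = 1L, is_mock = FALSE,
             stringsAsFactors = FALSE)
}

make_cq <- function(m, panel = "P1") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("r%02d", seq_len(ncol(m)))
  cq_matrix(m, make_ann(ncol(m), panel))
}

random_cq <- function(n_genes, n_rx, seed) {
  set.seed(seed)
  m <- matrix(runif(n_genes * n_rx, 10, 35), n_genes, n_rx)
  make_cq(m)
}

# independent footrule evaluation through explicit position tables
footrule_oracle <- function(a, b) {
  s <- 0
  for (g in a) s <- s + abs(which(a == g) - which(b == g))
  s
}

# all permutations of a character vector (independent of the package's
# internal generator): recursive insertion
perms_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in perms_of(x[-i])) out <- c(out, list(c(x[i], p)))
  out
}
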