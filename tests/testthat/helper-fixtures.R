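# shared fixture builders; everything is generated in code at test time

make_meta <- function(n_rep = 3, n_tp = 4) {
  tp <- paste0("t", seq_len(n_tp))
  data.frame(sample_id = paste0(rep(tp, each = n_rep), "_r", seq_len(n_rep)),
             time_point = rep(tp, each = n_rep),
             replicate = rep(seq_len(n_rep), n_tp))
}

# null NB count matrix with log-uniform library factors
make_null_counts <- function(n_genes, meta, mu = 100, alpha = 0.1,
                             lib = NULL) {
  if (is.null(lib)) lib <- exp(stats::runif(nrow(meta), log(0.5), log(2)))
  cn <- sapply(seq_len(nrow(meta)), function(j) {
    stats::rnbinom(n_genes, mu = mu * lib[j], size = 1 / alpha)
  })
  rownames(cn) <- sprintf("g%05d", seq_len(n_genes))
  colnames(cn) <- meta$sample_id
  cn
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# best cosine similarity matching of estimated to true components over all
# column permutations (k is small)
match_components <- function(S_est, S_true) {
  k <- ncol(S_true)
  perms <- gtools_permutations(k)
  best <- -Inf
  for (i in seq_len(nrow(perms))) {
    sims <- vapply(seq_len(k), function(j) {
      cosine(S_est[, perms[i, j]], S_true[, j])
    }, 1)
    if (min(sims) > best) best <- min(sims)
  }
  best
}

# all permutations of 1..n, plain recursion (n <= 5 here)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- (1:n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
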