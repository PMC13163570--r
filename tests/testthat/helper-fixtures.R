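# fixture builders shared across test files

# expression_matrix from a bare matrix, one tissue per sample unless given
make_em <- function(values, tissue = colnames(values), stage = NA,
                    source = "test") {
  expression_matrix(values,
                    data.frame(sample_id = colnames(values),
                               tissue = tissue, stage = stage,
                               source = source,
                               stringsAsFactors = FALSE))
}

# random gene x sample matrix with dimnames
rand_mat <- function(n_genes, n_samples, rfun = function(n) runif(n, 0, 20),
                     prefix = "g") {
  matrix(rfun(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(paste0(prefix, seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

# brute-force fold-rule TSG scan: the independent oracle for call_tsgs
brute_tsgs <- function(profile, fold = 3, min_tpm = 1) {
  out <- list()
  for (g in rownames(profile)) {
    v <- profile[g, ]
    if (max(v) < min_tpm) next
    for (t in colnames(profile)) {
      other <- max(v[setdiff(colnames(profile), t)])
      hit <- if (other == 0) v[t] >= min_tpm else v[t] >= fold * other
      if (hit) out[[length(out) + 1L]] <- c(g, t)
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, character(1L), collapse = " "))
}

# brute-force exclusivity scan: the independent oracle for call_markers
brute_markers <- function(profile, threshold = 1) {
  hits <- character(0)
  for (g in rownames(profile)) {
    expr <- profile[g, ] >= threshold
    if (sum(expr) == 1L)
      hits <- c(hits, paste(g, colnames(profile)[expr]))
  }
  sort(hits)
}

tsg_keys <- function(calls) sort(paste(calls$gene_id, calls$tissue))
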