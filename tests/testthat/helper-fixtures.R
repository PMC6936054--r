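# Small deterministic fixtures built in code.

# genes x samples matrix with dimnames
randomExpression <- function(m, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(m * n), m, n,
         dimnames = list(paste0("g", seq_len(m)), paste0("s", seq_len(n))))
}

# three samples on a line at positions 0, 1, 3 (one gene dimension is
# enough to fix the kNN structure; a constant second gene keeps m >= 2)
lineSamples <- function() {
  rbind(pos = c(0, 1, 3), const = c(0, 0, 0))
}

writeTSV <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# exhaustive best-mapping accuracy oracle (<= 7 classes)
permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call("c", lapply(seq_along(v), function(i)
    lapply(permutations(v[-i]), function(p) c(v[i], p))))
}

accOracle <- function(predicted, truth) {
  tab <- table(factor(predicted), factor(truth))
  k <- max(nrow(tab), ncol(tab))
  T2 <- matrix(0, k, k)
  T2[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  best <- max(vapply(permutations(seq_len(k)), function(p)
    sum(T2[cbind(seq_len(k), p)]), numeric(1)))
  100 * best / length(truth)
}

# largest principal angle (radians) between the column spans of A and B
maxPrincipalAngle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  max(acos(pmin(1, svd(crossprod(qa, qb))$d)))
}
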