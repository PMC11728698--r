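# Independent brute-force oracles. Deliberately naive (double loops,
# explicit set enumeration, textbook formulas): they share no code with
# the package implementations they check.

brute_bray <- function(u, v) {
  num <- 0; den <- 0
  for (i in seq_along(u)) {
    num <- num + abs(u[i] - v[i])
    den <- den + u[i] + v[i]
  }
  as.numeric(num / den)
}

# tips descending from `node`, by explicit recursive edge walk
brute_descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, brute_descendant_tips, tree = tree))
}

brute_unifrac <- function(u, v, tree) {
  num <- 0; den <- 0
  for (k in seq_len(nrow(tree$edge))) {
    tips <- brute_descendant_tips(tree, tree$edge[k, 2])
    mu <- sum(u[intersect(names(u), tips)])
    mv <- sum(v[intersect(names(v), tips)])
    b <- tree$edge.length[k]
    num <- num + b * abs(mu - mv)
    den <- den + b * (mu + mv)
  }
  num / den
}

brute_aitchison <- function(u, v, delta = NULL) {
  u <- u / sum(u); v <- v / sum(v)
  if (is.null(delta)) delta <- 1 / length(u)^2
  repl <- function(x) {
    z <- sum(x == 0)
    out <- numeric(length(x))
    for (i in seq_along(x))
      out[i] <- if (x[i] == 0) delta else x[i] * (1 - z * delta)
    out
  }
  cu <- log(repl(u)); cu <- cu - mean(cu)
  cv <- log(repl(v)); cv <- cv - mean(cv)
  s <- 0
  for (i in seq_along(cu)) s <- s + (cu[i] - cv[i])^2
  sqrt(s)
}

brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# all-pairs confused-species search by direct rule application
brute_confused_pairs <- function(ref, est, min_samples, r_threshold) {
  samples <- intersect(colnames(ref), colnames(est))
  feats <- union(rownames(ref), rownames(est))
  R <- matrix(0, length(feats), length(samples),
              dimnames = list(feats, samples))
  E <- R
  R[rownames(ref), ] <- unclass(ref)[, samples]
  E[rownames(est), ] <- unclass(est)[, samples]
  out <- NULL
  for (a in feats) for (b in feats) {
    if (a == b) next
    elig <- samples[R[a, ] > 0 & E[a, ] == 0 & R[b, ] == 0 & E[b, ] > 0]
    if (length(elig) < min_samples) next
    x <- R[a, elig]; y <- E[b, elig]
    if (length(unique(x)) < 3 || length(unique(y)) < 3) next
    r <- brute_pearson(x, y)
    if (is.na(r) || r <= r_threshold) next
    out <- rbind(out, data.frame(fn_feature = a, fp_feature = b,
                                 n_eligible = length(elig), pearson_r = r,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    return(data.frame(fn_feature = character(), fp_feature = character(),
                      n_eligible = integer(), pearson_r = numeric()))
  out <- out[order(-out$pearson_r, out$fn_feature, out$fp_feature), ]
  rownames(out) <- NULL
  out
}
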