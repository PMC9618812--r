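# Independent oracles used against the package's implementations.

## exhaustive-cutpoint ROC oracle: loops every candidate threshold and
## every observation; AUC via the Mann-Whitney U statistic (ties count 1/2)
roc_oracle <- function(values, labels) {
  y <- as.logical(labels)
  u <- sort(unique(values))
  thr <- if (length(u) > 1) c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
         else c(-Inf, Inf)
  se <- vapply(thr, function(t) mean(values[y] > t), numeric(1))
  sp <- vapply(thr, function(t) mean(values[!y] <= t), numeric(1))
  j <- se + sp - 1
  best <- which.max(j)
  pos <- values[y]; neg <- values[!y]
  auc <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
  list(threshold = thr[best], j = j[best], se = se[best], sp = sp[best],
       auc = auc)
}

## two-group log-rank by direct observed-minus-expected accounting
logrank_oracle <- function(times, events, group) {
  g1 <- sort(unique(group))[1]
  O <- E <- V <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

## Breslow log partial likelihood for a single covariate
breslow_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

## golden-section-free grid maximiser of the Breslow partial likelihood
breslow_grid_mle <- function(times, events, x, lo = -5, hi = 5) {
  for (step in c(0.01, 1e-4, 1e-6)) {
    grid <- seq(lo, hi, by = step)
    ll <- vapply(grid, breslow_loglik, numeric(1), times, events, x)
    b <- grid[which.max(ll)]
    lo <- b - 2 * step; hi <- b + 2 * step
  }
  b
}

## recursively collect (n, responders) of every node
tree_counts <- function(node) {
  if (node$type == "leaf")
    return(data.frame(type = "leaf", n = node$n, responders = node$responders))
  rbind(data.frame(type = "split", n = node$n, responders = node$responders),
        tree_counts(node$high), tree_counts(node$low))
}
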