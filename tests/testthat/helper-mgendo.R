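# Shared fixtures and independent brute-force oracles.

# A scaled-down study specification for fast tests. Donor-group sizes are
# kept small on purpose; tests that need the study's group sizes build their
# own spec.
tiny_spec <- function(..., seed = 1) {
  args <- list(
    n_train = c(EOMG = 4, LOMG = 4, CTRL = 4),
    n_val = c(EOMG = 3, LOMG = 3, CTRL = 0),
    cells_per_donor = c(train = 300, val = 300),
    thymus_cells_per_donor = 150,
    n_thymus = c(EOMG = 3, LOMG = 1),
    seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_spec, args)
}

# Hand-built cell table around a marker matrix.
make_cells <- function(x, lineage = "unassigned", donor_id = "D01",
                       cohort = "discovery", tissue = "blood") {
  x <- as.matrix(x)
  df <- data.frame(cell_id = sprintf("c%04d", seq_len(nrow(x))),
                   donor_id = donor_id, cohort = cohort, tissue = tissue,
                   lineage = lineage, cluster = NA_character_,
                   true_subpop = "background", stringsAsFactors = FALSE)
  out <- cbind(df, as.data.frame(x))
  attr(out, "transformed") <- TRUE
  out
}

# All permutations of 1..n as a matrix (rows); for small n only.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Exhaustive one-tailed rank-sum p-value: enumerate every assignment of the
# pooled values into the x positions.
enum_ranksum_p <- function(x, y, tail = "less") {
  pool <- c(x, y)
  m <- length(x)
  W_obs <- sum(rank(pool)[seq_len(m)])
  idx <- utils::combn(length(pool), m)
  r <- rank(pool)
  W_all <- apply(idx, 2, function(i) sum(r[i]))
  if (tail == "less") mean(W_all <= W_obs) else mean(W_all >= W_obs)
}

# Exhaustive two-sided Fisher p-value for a 2x2 table by enumerating the
# hypergeometric distribution over all tables with the observed margins.
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up written out directly.
enum_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[order(o)]
}

# Exhaustive two-sided Spearman permutation p-value (n <= 7).
enum_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- abs(cor(rx, ry))
  pm <- all_perms(length(y))
  rho_all <- apply(pm, 1, function(i) abs(cor(rx, ry[i])))
  mean(rho_all >= rho_obs - 1e-9)
}

# Pairwise-comparison AUC oracle (ties count half).
enum_auc <- function(scores, labels, positive = "EOMG") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}
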