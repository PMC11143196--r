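# shared fixtures and independent oracles (kept deliberately naive; they are
# the reference implementations the package code is checked against)

# a small valid composition concentrated on a few populations
tiny_composition <- function() {
  comp <- c(tumor_b = 0.05, tme_b = 0.25, helper_t = 0.3, tfh = 0.15,
            macrophage = 0.1, other = 0.15)
  comp
}

tiny_config <- function(n_cells = 300, seed = 1, architecture = "diffuse", ...) {
  tissue_config(architecture = architecture, roi_size = c(300, 300),
                n_cells = n_cells, composition = tiny_composition(),
                seed = seed, ...)
}

# brute-force all-pairs annulus edges; returns sorted "i|j" keys (i < j row idx)
brute_force_edges <- function(x, y, d_min, d_max) {
  n <- length(x)
  keys <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d >= d_min && d <= d_max) keys <- c(keys, paste(i, j, sep = "|"))
    }
  }
  sort(keys)
}

# independent exact rank-sum oracle: recursive enumeration of which pooled
# positions belong to sample 1 (structurally different from the package's
# combn-based path)
oracle_rank_sum_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y), ties.method = "average")
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  sums <- c()
  rec <- function(start, left, acc) {
    if (left == 0L) { sums <<- c(sums, acc); return(invisible()) }
    for (k in start:(n - left + 1L)) rec(k + 1L, left - 1L, acc + r[k])
  }
  rec(1L, n1, 0)
  eps <- 1e-9
  switch(alternative,
         two.sided = mean(abs(sums - mu) >= abs(W - mu) - eps),
         greater = mean(sums >= W - eps),
         less = mean(sums <= W + eps))
}

# flood-fill count of 4-connected components above a threshold
count_components <- function(m, thr) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  for (r0 in seq_len(nrow(m))) for (c0 in seq_len(ncol(m))) {
    if (m[r0, c0] > thr && lab[r0, c0] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(r0, c0)); lab[r0, c0] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          rr <- p[1] + d[1]; cc <- p[2] + d[2]
          if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) &&
              m[rr, cc] > thr && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  nxt
}

# hand-built cell table from a boolean marker-state matrix; positives get a
# bright raw intensity, negatives a dim one, with fixed thresholds in between
state_cells <- function(states) {
  mk <- codex_markers()
  n <- nrow(states)
  dt <- data.table::data.table(
    cell_id = sprintf("s%03d", seq_len(n)), roi_id = "roiA", case_id = "caseA",
    group = "g", x_um = seq_len(n) * 10, y_um = rep(5, n))
  for (m in mk) {
    col <- if (m %in% colnames(states)) states[, m] else rep(FALSE, n)
    dt[[m]] <- ifelse(col, 1000, 1)
  }
  as_cell_table(dt, markers = mk)
}

fixed_thresholds <- function() {
  mk <- codex_markers()
  threshold_set(stats::setNames(rep(asinh(100 / 150), length(mk)), mk), 150)
}

random_states <- function(n, seed) {
  set.seed(seed)
  mk <- codex_markers()
  m <- matrix(runif(n * length(mk)) < 0.3, n, length(mk),
              dimnames = list(NULL, mk))
  m
}

# reference assignment: literal rule scan, most-required-then-priority
oracle_assign <- function(states, schema) {
  apply(states, 1, function(st) {
    best <- "other"; best_req <- -1; best_pr <- Inf
    for (r in schema$rules) {
      if (all(st[r$required]) && !any(st[r$forbidden])) {
        nr <- length(r$required)
        if (nr > best_req || (nr == best_req && r$priority < best_pr)) {
          best <- r$name; best_req <- nr; best_pr <- r$priority
        }
      }
    }
    best
  })
}
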