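# Independent oracles, written deliberately as plain loops / generic
# numerics so they share no code path with the package internals.

# ---- roster / record fixtures -------------------------------------------

toy_roster <- function(n_m = 2, n_f = 2, group = "g1", min_age = 4,
                       ages = NULL, lines = NULL) {
  n <- n_m + n_f
  ids <- sprintf("%s%02d", toupper(group), seq_len(n))
  roster(ids,
         c(rep("M", n_m), rep("F", n_f)),
         if (is.null(ages)) seq(10, 10 + n - 1) else ages,
         group,
         if (is.null(lines)) paste0("L", seq_len(n)) else lines,
         min_age = min_age)
}

# hand-build focal records from a compact spec list:
# list(list(date, focal, w10, w1, gr), ...)
toy_records <- function(rows, roster) {
  focal_records(
    date = vapply(rows, `[[`, character(1), 1),
    focal_id = vapply(rows, `[[`, character(1), 2),
    within10m = lapply(rows, function(r) r[[3]]),
    within1m = lapply(rows, function(r) if (length(r) >= 4) r[[4]] else character()),
    grooming = lapply(rows, function(r) if (length(r) >= 5) r[[5]] else character()),
    roster = roster)
}

# random small focal-record fixture, independent of the generator module
random_records <- function(roster, n_days, seed, p_assoc = 0.3,
                           p_close = 0.5, p_groom = 0.5) {
  set.seed(seed)
  ids <- roster$id
  rows <- list()
  for (d in seq_len(n_days)) {
    date <- as.character(as.Date("2013-07-01") + d - 1)
    for (f in sample(ids, sample(1:length(ids), 1))) {
      others <- setdiff(ids, f)
      w10 <- others[runif(length(others)) < p_assoc]
      w1 <- w10[runif(length(w10)) < p_close]
      gr <- w1[runif(length(w1)) < p_groom]
      rows[[length(rows) + 1L]] <- list(date, f, w10, w1, gr)
    }
  }
  toy_records(rows, roster)
}

# ---- brute-force simple-ratio tally -------------------------------------

# Exhaustive per-day re-tally of one dyad straight from the raw records:
# no matrices, no vectorization, the most literal reading of the index.
oracle_sri <- function(records, measure, id_a, id_b) {
  df <- as.data.frame(records)
  col <- c(party10m = "within10m", direct1m = "within1m",
           grooming = "grooming")[[measure]]
  days <- unique(df$date)
  x <- y_a <- y_b <- y_ab <- 0
  for (day in days) {
    rs <- df[df$date == day, , drop = FALSE]
    seen <- function(id) {
      if (any(rs$focal_id == id)) return(TRUE)
      for (i in seq_len(nrow(rs))) {
        if (id %in% strsplit(rs$within10m[i], ";")[[1]]) return(TRUE)
      }
      FALSE
    }
    assoc <- FALSE
    for (i in seq_len(nrow(rs))) {
      members <- strsplit(rs[[col]][i], ";")[[1]]
      if (rs$focal_id[i] == id_a && id_b %in% members) assoc <- TRUE
      if (rs$focal_id[i] == id_b && id_a %in% members) assoc <- TRUE
    }
    sa <- seen(id_a); sb <- seen(id_b)
    if (assoc) x <- x + 1
    else if (sa && sb) y_ab <- y_ab + 1
    else if (sa) y_a <- y_a + 1
    else if (sb) y_b <- y_b + 1
  }
  den <- x + y_a + y_b + y_ab
  list(x = x, y_a = y_a, y_b = y_b, y_ab = y_ab,
       sri = if (den == 0) 0 else x / den)
}

# ---- fixed-effects beta regression ML (no random effects) ---------------

oracle_beta_reg <- function(y, X) {
  nll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    phi <- exp(par[ncol(X) + 1])
    mu <- plogis(drop(X %*% beta))
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  o <- stats::optim(c(rep(0, ncol(X)), 1), nll, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  list(beta = o$par[seq_len(ncol(X))], phi = exp(o$par[ncol(X) + 1]),
       loglik = -o$value)
}

# ---- dense Gauss-Hermite marginal likelihood ----------------------------

gh_rule <- function(k) {
  # Golub-Welsch nodes/weights for the e^{-x^2} weight function
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Marginal negative log-likelihood by tensor-product quadrature over the
# random-effect dimensions actually used (unused role levels integrate
# to one). Feasible for <= 5 active dimensions.
oracle_gh_nll <- function(theta, y, X, ia, ib, family = "beta", k = 21) {
  p <- ncol(X)
  if (family == "beta") { phi <- exp(theta[p + 1]); off <- p + 1 } else {
    phi <- NA; off <- p }
  sa <- exp(theta[off + 1]); sb <- exp(theta[off + 2])
  ua_lv <- sort(unique(ia)); ub_lv <- sort(unique(ib))
  qa <- length(ua_lv); qb <- length(ub_lv)
  stopifnot(qa + qb <= 6)
  rule <- gh_rule(k)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), qa + qb))
  logw <- rowSums(matrix(log(rule$weights[as.matrix(grid)] / sqrt(pi)),
                         nrow(grid)))
  Xb <- drop(X %*% theta[seq_len(p)])
  ll <- logw
  for (i in seq_along(y)) {
    ca <- match(ia[i], ua_lv)
    cb <- qa + match(ib[i], ub_lv)
    eta <- Xb[i] + sqrt(2) * sa * rule$nodes[grid[[ca]]] +
      sqrt(2) * sb * rule$nodes[grid[[cb]]]
    mu <- plogis(eta)
    ll <- ll + if (family == "beta") {
      stats::dbeta(y[i], mu * phi, (1 - mu) * phi, log = TRUE)
    } else {
      stats::dbinom(y[i], 1, mu, log = TRUE)
    }
  }
  M <- max(ll)
  -(M + log(sum(exp(ll - M))))
}

# ---- exhaustive partition search for the Potts Hamiltonian --------------

# all set partitions of 1..n via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(mx + 1L)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(), 0L)
  out
}

# independent Hamiltonian evaluation from an adjacency matrix
oracle_hamiltonian <- function(A, membership, gamma = 1) {
  s <- rowSums(A)
  two_m <- sum(s)
  H <- 0
  n <- nrow(A)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (membership[i] == membership[j]) {
        H <- H - (A[i, j] - gamma * s[i] * s[j] / two_m)
      }
    }
  }
  H
}

oracle_best_partition <- function(A, gamma = 1) {
  parts <- all_partitions(nrow(A))
  hs <- vapply(parts, function(p) oracle_hamiltonian(A, p, gamma), numeric(1))
  list(H = min(hs), membership = parts[[which.min(hs)]])
}

# small two-group generator config used across tests
test_config <- function(n_per_sex = 3, n_days = 15, seed = 1, ...) {
  generator_config(groups = list(
    list(group_id = "g1", n_males = n_per_sex, n_females = n_per_sex,
         n_maternal_lines = 2),
    list(group_id = "g2", n_males = n_per_sex, n_females = n_per_sex,
         n_maternal_lines = 2)),
    n_days = n_days, seed = seed, ...)
}
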