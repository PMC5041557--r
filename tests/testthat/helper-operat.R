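# Shared fixtures and independent brute-force oracles.

default_spec <- default_instrument()

## an assessment with every item at its most (or least) desirable state
extreme_assessment <- function(spec, state = c("best", "worst"),
                               area_id = "AA1 1AA") {
  state <- match.arg(state)
  obs <- list(area_id = area_id)
  for (i in seq_len(nrow(spec$items))) {
    it <- spec$items[i, ]
    want_feature <- (it$desirable_direction == "presence_good") ==
      (state == "best")
    obs[[it$item_id]] <- switch(it$value_kind,
      binary = as.numeric(want_feature),
      proportion = as.numeric(want_feature),
      ordinal = if (want_feature) it$ordinal_levels else 1)
  }
  obs
}

## a random in-range assessment
random_assessment <- function(spec, area_id = "AA1 1AA") {
  obs <- list(area_id = area_id)
  for (i in seq_len(nrow(spec$items))) {
    it <- spec$items[i, ]
    obs[[it$item_id]] <- switch(it$value_kind,
      binary = sample(0:1, 1),
      proportion = runif(1),
      ordinal = sample(seq_len(it$ordinal_levels), 1))
  }
  obs
}

## independent total-score oracle: explicit per-item contribution sum
oracle_total <- function(spec, obs) {
  total <- 0
  for (i in seq_len(nrow(spec$items))) {
    it <- spec$items[i, ]
    d <- spec$domains[spec$domains$domain_id == it$domain_id, ]
    v <- obs[[it$item_id]]
    u <- switch(it$value_kind,
      binary = v, proportion = v,
      ordinal = (v - 1) / (it$ordinal_levels - 1))
    r <- if (it$desirable_direction == "presence_good") 1 - u else u
    total <- total + r * it$multiplier / (d$raw_max - d$raw_min) *
      spec$chi * d$eag_weight
  }
  total
}

## exhaustive-pair Kendall tau-b oracle with tie correction
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- txy <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) txy <- txy + 1
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx - txy) * (n0 - ty - txy))
}

## brute-force Krippendorff alpha: enumerate all within-unit ordered pairs
## for observed disagreement and all cross-marginal pairs for expected
oracle_krippendorff <- function(M, metric) {
  vals_all <- as.vector(M[!is.na(M)])
  units <- lapply(seq_len(nrow(M)), function(u) {
    r <- M[u, ]; r[!is.na(r)]
  })
  units <- units[vapply(units, length, integer(1)) >= 2]
  pooled <- unlist(units)
  vals <- sort(unique(pooled))
  ## marginal coincidence counts (needed for the ordinal metric)
  nc <- vapply(vals, function(v) sum(pooled == v), numeric(1))
  delta <- function(a, b) {
    if (metric == "nominal") as.numeric(a != b)
    else if (metric == "interval") (a - b)^2
    else {
      ia <- which(vals == min(a, b)); ib <- which(vals == max(a, b))
      if (ia == ib) 0 else (sum(nc[ia:ib]) - (nc[ia] + nc[ib]) / 2)^2
    }
  }
  num <- 0; npairs <- 0
  for (r in units) {
    m <- length(r)
    for (a in seq_len(m)) for (b in seq_len(m)) if (a != b) {
      num <- num + delta(r[a], r[b]) / (m - 1)
      npairs <- npairs + 1 / (m - 1)
    }
  }
  Do <- num / sum(nc)
  De_num <- 0
  for (a in seq_along(vals)) for (b in seq_along(vals))
    De_num <- De_num + nc[a] * nc[b] * delta(vals[a], vals[b])
  De <- De_num / (sum(nc) * (sum(nc) - 1))
  1 - Do / De
}

## brute-force 9-point median with round-toward-midpoint tie rule
oracle_nine_median <- function(s) {
  s <- sort(s); n <- length(s)
  if (n %% 2 == 1) return(s[(n + 1) / 2])
  m <- (s[n / 2] + s[n / 2 + 1]) / 2
  if (m == floor(m)) return(m)
  cands <- c(floor(m), ceiling(m))
  cands[which.min(abs(cands - 5))]
}
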