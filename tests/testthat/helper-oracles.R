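# Independent brute-force oracles, coded from the definitions without reuse
# of package internals, plus small fixture builders.

make_track <- function(x, y, frame_interval = 10, track_id = 1L) {
  n <- length(x)
  data.frame(track_id = track_id, frame = 0:(n - 1),
             t = (0:(n - 1)) * frame_interval, x = x, y = y, quality = 0)
}

random_track <- function(T, frame_interval = 10) {
  make_track(cumsum(rnorm(T)), cumsum(rnorm(T)), frame_interval)
}

# --- migration-metric oracles (explicit loops over the definitions) -------

o_path <- function(tr) {
  s <- 0
  for (i in 2:nrow(tr))
    s <- s + sqrt((tr$x[i] - tr$x[i - 1])^2 + (tr$y[i] - tr$y[i - 1])^2)
  s
}

o_disp <- function(tr) {
  n <- nrow(tr)
  sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2)
}

o_maxdist <- function(tr) {
  best <- 0
  for (i in 1:(nrow(tr) - 1)) for (j in (i + 1):nrow(tr)) {
    d <- sqrt((tr$x[i] - tr$x[j])^2 + (tr$y[i] - tr$y[j])^2)
    if (d > best) best <- d
  }
  best
}

o_median_speed <- function(tr, dt) {
  sp <- numeric(0)
  for (i in 2:nrow(tr))
    sp <- c(sp, sqrt((tr$x[i] - tr$x[i - 1])^2 + (tr$y[i] - tr$y[i - 1])^2) / dt)
  sort(sp)[c(ceiling(length(sp) / 2), floor(length(sp) / 2) + 1)] |> mean()
}

o_dir_curve <- function(tr) {
  n <- nrow(tr)
  out <- numeric(n - 1)
  for (k in 2:n) {
    D <- 0
    for (i in 2:k)
      D <- D + sqrt((tr$x[i] - tr$x[i - 1])^2 + (tr$y[i] - tr$y[i - 1])^2)
    d <- sqrt((tr$x[k] - tr$x[1])^2 + (tr$y[k] - tr$y[1])^2)
    out[k - 1] <- if (D > 0) d / D else NA_real_
  }
  out
}

o_msd <- function(tr) {
  n <- nrow(tr)
  out <- numeric(n - 1)
  for (lag in 1:(n - 1)) {
    acc <- 0
    cnt <- 0
    for (i in 1:(n - lag)) {
      acc <- acc + (tr$x[i + lag] - tr$x[i])^2 + (tr$y[i + lag] - tr$y[i])^2
      cnt <- cnt + 1
    }
    out[lag] <- acc / cnt
  }
  out
}

# --- statistics oracles ---------------------------------------------------

o_anova_ss <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  sst <- sum((values - gm)^2)
  ssb <- 0
  ssw <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  k <- length(unique(groups))
  n <- length(values)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  list(ssb = ssb, ssw = ssw, sst = sst,
       F = msb / msw, p = pf(msb / msw, k - 1, n - k, lower.tail = FALSE))
}

# Tukey-Kramer from first principles: studentized range on MSW from the
# one-way ANOVA, with the Kramer average of 1/n_i for unequal group sizes.
o_tukey <- function(values, groups) {
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  k <- length(levs)
  n <- length(values)
  ssw <- 0
  for (g in levs) {
    v <- values[groups == g]
    ssw <- ssw + sum((v - mean(v))^2)
  }
  msw <- ssw / (n - k)
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    vi <- values[groups == levs[i]]
    vj <- values[groups == levs[j]]
    se <- sqrt(msw / 2 * (1 / length(vi) + 1 / length(vj)))
    q <- abs(mean(vj) - mean(vi)) / se
    p <- ptukey(q, k, n - k, lower.tail = FALSE)
    out <- rbind(out, data.frame(a = levs[i], b = levs[j], p = p))
  }
  out
}

# --- image oracles --------------------------------------------------------

# Huang-Wang fuzziness from the definition, evaluated independently for a
# single candidate cut; the oracle minimizer scans all cuts.
o_huang_fuzziness <- function(counts, levels, t_level) {
  lo <- levels <= t_level
  if (!any(counts[lo] > 0) || !any(counts[!lo] > 0)) return(Inf)
  occ <- levels[counts > 0]
  C <- max(occ) - min(occ)
  mu0 <- sum(counts[lo] * levels[lo]) / sum(counts[lo])
  mu1 <- sum(counts[!lo] * levels[!lo]) / sum(counts[!lo])
  mu <- ifelse(lo, mu0, mu1)
  u <- 1 / (1 + abs(levels - mu) / C)
  s <- ifelse(u > 0 & u < 1, -u * log(u) - (1 - u) * log(1 - u), 0)
  sum(counts * s)
}

o_huang_threshold <- function(counts, levels) {
  occ <- which(counts > 0)
  cand <- levels[occ[1]:(occ[length(occ)] - 1)]
  fuzz <- vapply(cand, function(t) o_huang_fuzziness(counts, levels, t),
                 numeric(1))
  cand[which.min(fuzz)]  # which.min takes the first (lowest) minimizer
}

# Prominence by exhaustive saddle search: for each local maximum, the saddle
# to any higher maximum is the highest level L at which it is connected
# (8-neighborhood, pixels >= L) to a strictly higher maximum.
o_local_maxima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- NULL
  for (r in 1:nr) for (c in 1:nc) {
    v <- img[r, c]
    is_max <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (img[rr, cc] > v) is_max <- FALSE
    }
    if (is_max) out <- rbind(out, data.frame(row = r, col = c, value = v))
  }
  out
}

o_connected <- function(img, level, p1, p2) {
  keep <- img >= level
  if (!keep[p1[1], p1[2]] || !keep[p2[1], p2[2]]) return(FALSE)
  nr <- nrow(img); nc <- ncol(img)
  seen <- matrix(FALSE, nr, nc)
  stack <- list(p1)
  seen[p1[1], p1[2]] <- TRUE
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (p[1] == p2[1] && p[2] == p2[2]) return(TRUE)
    for (dr in -1:1) for (dc in -1:1) {
      rr <- p[1] + dr; cc <- p[2] + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (keep[rr, cc] && !seen[rr, cc]) {
        seen[rr, cc] <- TRUE
        stack[[length(stack) + 1]] <- c(rr, cc)
      }
    }
  }
  FALSE
}

# returns data frame of maxima (deduplicated plateaus by value+component)
# with their prominences
o_prominences <- function(img) {
  mx <- o_local_maxima(img)
  # merge plateau maxima: group connected equal-valued maxima
  used <- rep(FALSE, nrow(mx))
  groups <- list()
  for (i in seq_len(nrow(mx))) {
    if (used[i]) next
    grp <- i
    used[i] <- TRUE
    repeat {
      grew <- FALSE
      for (j in seq_len(nrow(mx))) {
        if (used[j] || mx$value[j] != mx$value[i]) next
        if (any(vapply(grp, function(g)
          o_connected(img, mx$value[i], c(mx$row[g], mx$col[g]),
                      c(mx$row[j], mx$col[j])), logical(1)))) {
          grp <- c(grp, j)
          used[j] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    groups[[length(groups) + 1]] <- grp
  }
  levels_all <- sort(unique(as.vector(img)), decreasing = TRUE)
  out <- NULL
  for (g in groups) {
    v <- mx$value[g[1]]
    higher <- which(mx$value > v)
    if (!length(higher)) {
      prom <- v - min(img)
    } else {
      saddle <- -Inf
      for (L in levels_all) {
        if (L > v) next
        conn <- FALSE
        for (h in higher) {
          if (o_connected(img, L, c(mx$row[g[1]], mx$col[g[1]]),
                          c(mx$row[h], mx$col[h]))) {
            conn <- TRUE
            break
          }
        }
        if (conn) {
          saddle <- L
          break
        }
      }
      prom <- v - saddle
    }
    out <- rbind(out, data.frame(
      row = mean(mx$row[g]), col = mean(mx$col[g]), value = v,
      prominence = prom))
  }
  out
}

# --- exhaustive assignment oracle ----------------------------------------

o_best_matching <- function(a, b, radius) {
  n1 <- nrow(a); n2 <- nrow(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  best <- NULL
  best_key <- c(-1, Inf)  # maximize links, then minimize cost
  assignments <- function(rows, taken, cur) {
    if (!length(rows)) {
      links <- sum(!is.na(cur))
      cost <- sum(d2[cbind(which(!is.na(cur)), cur[!is.na(cur)])])
      if (links > best_key[1] ||
          (links == best_key[1] && cost < best_key[2] - 1e-12)) {
        best_key <<- c(links, cost)
        best <<- cur
      }
      return(invisible())
    }
    r <- rows[1]
    assignments(rows[-1], taken, c(cur, NA_integer_))
    for (j in seq_len(n2)) {
      if (j %in% taken) next
      if (d2[r, j] <= radius^2)
        assignments(rows[-1], c(taken, j), c(cur, j))
    }
  }
  assignments(seq_len(n1), integer(0), integer(0))
  best
}
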