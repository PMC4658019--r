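# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (explicit loops, naive transforms) and
# share no code with the package implementations they check.

# --- GLCM: exhaustive pair enumeration over every voxel pair ----------
oracle_glcm_matrix <- function(rescaled, levels) {
  q <- matrix(pmin(rescaled %/% (256 %/% levels) + 1, levels), 8, 8)
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  acc <- matrix(0, levels, levels)
  for (off in offsets) {
    m <- matrix(0, levels, levels)
    for (r in 1:8) for (cc in 1:8) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= 8 && c2 >= 1 && c2 <= 8) {
        m[q[r, cc], q[r2, c2]] <- m[q[r, cc], q[r2, c2]] + 1
        m[q[r2, c2], q[r, cc]] <- m[q[r2, c2], q[r, cc]] + 1
      }
    }
    acc <- acc + m / sum(m)
  }
  acc / 4
}

oracle_glcm_features <- function(rescaled, levels = 16) {
  p <- oracle_glcm_matrix(rescaled, levels)
  g <- levels
  ent <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }
  px <- rowSums(p)
  mu <- sum((1:g) * px); sdv <- sqrt(sum(((1:g) - mu)^2 * px))
  e <- h <- dis <- con <- v <- cor <- 0
  for (i in 1:g) for (j in 1:g) {
    e <- e + p[i, j]^2
    h <- h + p[i, j] / (1 + (i - j)^2)
    dis <- dis + p[i, j] * abs(i - j)
    con <- con + p[i, j] * (i - j)^2
    v <- v + (i - mu)^2 * p[i, j]
    cor <- cor + (i - mu) * (j - mu) * p[i, j]
  }
  cor <- if (sdv > 0) cor / sdv^2 else 0
  ps <- rep(0, 2 * g); pd <- rep(0, g)
  for (i in 1:g) for (j in 1:g) {
    ps[i + j] <- ps[i + j] + p[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
  }
  sa <- sum((2:(2 * g)) * ps[2:(2 * g)])
  sv <- sum(((2:(2 * g)) - sa)^2 * ps[2:(2 * g)])
  mu_d <- sum((0:(g - 1)) * pd)
  dv <- sum(((0:(g - 1)) - mu_d)^2 * pd)
  hxy1 <- 0
  for (i in 1:g) for (j in 1:g)
    if (p[i, j] > 0 && px[i] * px[j] > 0)
      hxy1 <- hxy1 - p[i, j] * log(px[i] * px[j])
  hx <- ent(px)
  imc1 <- if (hx > 0) (ent(p) - hxy1) / hx else 0
  c(energy = e, entropy = ent(p), homogeneity = h, dissimilarity = dis,
    correlation = cor, contrast = con, variance = v, sum_average = sa,
    sum_variance = sv, sum_entropy = ent(ps), diff_variance = dv,
    diff_entropy = ent(pd), imc1 = imc1)
}

# --- LBP: explicit rotation enumeration for transition counting -------
oracle_bilinear <- function(x, r, cc) {
  r0 <- floor(r); c0 <- floor(cc)
  fr <- r - r0; fc <- cc - c0
  r1 <- min(r0 + 1, nrow(x)); c1 <- min(c0 + 1, ncol(x))
  x[r0, c0] * (1 - fr) * (1 - fc) + x[r1, c0] * fr * (1 - fc) +
    x[r0, c1] * (1 - fr) * fc + x[r1, c1] * fr * fc
}

oracle_lbp_features <- function(rescaled) {
  hist12 <- rep(0, 12)
  edges <- floor((0:11) * 25 / 11)
  for (r in 4:5) for (cc in 4:5) {
    bits <- integer(24)
    for (k in 1:24) {
      th <- 2 * pi * (k - 1) / 24
      bits[k] <- as.integer(
        oracle_bilinear(rescaled, r - 3 * sin(th), cc + 3 * cos(th)) >=
          rescaled[r, cc])
    }
    # transitions counted by explicitly comparing every rotation with
    # its one-step rotation at position 1
    trans <- 0
    for (rot in 0:23) {
      rolled <- bits[((0:23 + rot) %% 24) + 1]
      next_rolled <- bits[((0:23 + rot + 1) %% 24) + 1]
      if (rolled[1] != next_rolled[1]) trans <- trans + 1
    }
    bin <- if (trans <= 2) max(which(edges <= sum(bits))) else 12
    hist12[bin] <- hist12[bin] + 1
  }
  hist12 / sum(hist12)
}

# --- DOST: naive O(N^4) double-sum DFT --------------------------------
oracle_dft2 <- function(x) {
  n <- nrow(x)
  out <- matrix(complex(real = 0), n, n)
  for (u in 0:(n - 1)) for (v in 0:(n - 1)) {
    s <- 0 + 0i
    for (a in 0:(n - 1)) for (b in 0:(n - 1))
      s <- s + x[a + 1, b + 1] *
        exp(-2i * pi * (u * a / n + v * b / n))
    out[u + 1, v + 1] <- s
  }
  out
}

oracle_dost_features <- function(raw) {
  amp <- Mod(oracle_dft2(raw))
  freq <- c(0:3, -4:-1)
  secs <- list(0, 1, -1, c(2, 3), c(-2, -3), -4)
  ords <- c(0, 1, 1, 2, 2, 3)
  sec_of <- integer(8)
  for (s in seq_along(secs)) sec_of[freq %in% secs[[s]]] <- s
  h <- matrix(0, 6, 6); ro <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6) {
    h[a, b] <- mean(amp[sec_of == a, sec_of == b])
    ro[a, b] <- max(ords[a], ords[b])
  }
  f <- c(h[ro == 0], mean(h[ro == 1]), mean(h[ro == 2]), mean(h[ro == 3]))
  en <- f^2
  se <- if (sum(en) > 0) {
    pr <- en[en > 0] / sum(en); -sum(pr * log(pr)) / log(4)
  } else 0
  c(f, se)
}

# --- diagonal-Gaussian classifier oracle ------------------------------
oracle_diag_posterior <- function(x_train, y_train, x_new, type = "dlda",
                                  eps = 1e-9) {
  cls <- c("high", "low")
  n <- nrow(x_train)
  stats_c <- lapply(cls, function(cl) {
    xc <- x_train[y_train == cl, , drop = FALSE]
    list(mu = colMeans(xc),
         ssq = colSums(sweep(xc, 2, colMeans(xc))^2),
         n = nrow(xc))
  })
  names(stats_c) <- cls
  lik <- vapply(cls, function(cl) {
    s2 <- if (type == "dlda")
      pmax((stats_c$high$ssq + stats_c$low$ssq) / (n - 2), eps)
    else pmax(stats_c[[cl]]$ssq / max(stats_c[[cl]]$n - 1, 1), eps)
    vapply(seq_len(nrow(x_new)), function(i)
      sum(stats::dnorm(x_new[i, ], stats_c[[cl]]$mu, sqrt(s2),
                       log = TRUE)) + log(stats_c[[cl]]$n / n),
      numeric(1))
  }, numeric(nrow(x_new)))
  lik <- matrix(lik, ncol = 2, dimnames = list(NULL, cls))
  post <- exp(lik - apply(lik, 1, max))
  post / rowSums(post)
}

# --- LOOCV oracle: explicit fold materialization ----------------------
oracle_loocv_dlda <- function(x, y) {
  n <- nrow(x)
  correct <- 0
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      pred <- ytr[1]
    } else {
      post <- oracle_diag_posterior(xtr, ytr, x[i, , drop = FALSE])
      pred <- if (post[1, "high"] > post[1, "low"]) "high" else "low"
    }
    if (pred == y[i]) correct <- correct + 1
  }
  correct / n
}

# --- greedy selection oracle ------------------------------------------
oracle_greedy_select <- function(x, y, gain_threshold = 0.01) {
  cand <- colnames(x)
  sel <- character(0)
  cur <- max(table(y)) / length(y)
  repeat {
    rem <- setdiff(cand, sel)
    if (!length(rem)) break
    accs <- vapply(rem, function(f)
      oracle_loocv_dlda(x[, c(sel, f), drop = FALSE], y), numeric(1))
    if (max(accs) - cur < gain_threshold) break
    sel <- c(sel, rem[which.max(accs)])
    cur <- max(accs)
  }
  sel
}

# --- minimal-removal oracle over all subsets --------------------------
oracle_min_removal <- function(sites, min_mm, max_mm, voxel_size_mm) {
  n <- length(sites)
  ctr <- t(sapply(sites, function(s)
    c(s$slice * voxel_size_mm[1],
      (s$row0 + 3.5) * voxel_size_mm[2],
      (s$col0 + 3.5) * voxel_size_mm[3])))
  pid <- sapply(sites, `[[`, "patient_id")
  bad <- function(keep) {
    k <- which(keep)
    for (a in k) for (b in k) if (a < b && pid[a] == pid[b]) {
      d <- sqrt(sum((ctr[a, ] - ctr[b, ])^2))
      if (d >= min_mm && d < max_mm) return(TRUE)
    }
    FALSE
  }
  best <- 0
  for (code in 0:(2^n - 1)) {
    keep <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (sum(keep) > best && !bad(keep)) best <- sum(keep)
  }
  best
}

random_patch <- function(contrast = "T1+C") {
  roi_patch(contrast, matrix(stats::rnorm(64), 8, 8))
}

rotate90 <- function(m) t(m)[, nrow(m):1]
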