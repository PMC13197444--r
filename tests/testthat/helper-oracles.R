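# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as naive loops, sharing no code with the
# package internals.

# Flood-fill connected-component labelling (BFS, explicit queue).
oracle_flood_fill <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, dm)
  nxt <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, dm)
      for (r in seq_len(nrow(offs))) {
        n <- ijk + offs[r, ]
        if (any(n < 1) || any(n > dm)) next
        lin <- (n[3] - 1) * dm[1] * dm[2] + (n[2] - 1) * dm[1] + n[1]
        if (mask[lin] != 0 && lab[lin] == 0L) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# Are two labelings the same partition (ignoring label numbering)?
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  sel <- a > 0
  key <- paste(a[sel], b[sel])
  map_ab <- unique(cbind(a[sel], b[sel]))
  !any(duplicated(map_ab[, 1])) && !any(duplicated(map_ab[, 2]))
}

# Voxel-loop pairwise intersection counts between two label arrays.
oracle_overlap_counts <- function(lab_a, lab_b) {
  counts <- list()
  for (v in seq_along(lab_a)) {
    if (lab_a[v] > 0 && lab_b[v] > 0) {
      key <- paste(lab_a[v], lab_b[v])
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  counts
}

# Voxel-loop concordance categories (min-volume denominator, strict >).
oracle_categories <- function(lab_a, lab_b, threshold = 0.10) {
  counts <- oracle_overlap_counts(lab_a, lab_b)
  vol_a <- table(lab_a[lab_a > 0]); vol_b <- table(lab_b[lab_b > 0])
  conc_a <- conc_b <- integer(0)
  for (key in names(counts)) {
    ab <- as.integer(strsplit(key, " ")[[1]])
    frac <- counts[[key]] / min(vol_a[[as.character(ab[1])]],
                                vol_b[[as.character(ab[2])]])
    if (frac > threshold) {
      conc_a <- union(conc_a, ab[1]); conc_b <- union(conc_b, ab[2])
    }
  }
  list(
    cat_a = ifelse(sort(unique(lab_a[lab_a > 0])) %in% conc_a,
                   "concordant", "A_only"),
    cat_b = ifelse(sort(unique(lab_b[lab_b > 0])) %in% conc_b,
                   "concordant", "B_only"))
}

# Voxel-loop site labels (>= 10% of lesion voxels in bone -> medullary).
oracle_sites <- function(lab, bone, threshold = 0.10) {
  labs <- sort(unique(lab[lab > 0]))
  vapply(labs, function(l) {
    vox <- which(lab == l)
    if (sum(bone[vox] > 0) / length(vox) >= threshold) "medullary"
    else "extramedullary"
  }, character(1))
}

# Manual Welch t-test from the closed formulas.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Manual Kaplan-Meier product-limit estimate at each distinct event time.
oracle_km <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# Manual two-group log-rank statistic from the risk-set table.
oracle_logrank <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  o1 <- ex1 <- v1 <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d2 <- sum(t2 == tt & e2 == 1)
    d <- d1 + d2
    o1 <- o1 + d1
    ex1 <- ex1 + d * n1 / n
    if (n > 1) v1 <- v1 + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- (o1 - ex1)^2 / v1
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Exponential-weight Shapley values by full enumeration over ALL features,
# with an iterative (stack-based) path-dependent expectation, independent
# of the package's recursive implementation.
oracle_shapley <- function(st, x_row, features) {
  expectation <- function(S) {
    total <- 0
    stack <- list(list(i = 1L, w = 1))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- top$i; w <- top$w
      if (st$is_leaf[i]) {
        total <- total + w * st$prob[i]
      } else if (st$var[i] %in% S) {
        val <- x_row[[st$var[i]]]
        left <- if (is.na(val)) st$majority_left[i]
        else if (st$left_lt[i]) val < st$threshold[i]
        else val >= st$threshold[i]
        stack[[length(stack) + 1L]] <-
          list(i = if (left) st$left[i] else st$right[i], w = w)
      } else {
        stack[[length(stack) + 1L]] <-
          list(i = st$left[i], w = w * st$n[st$left[i]] / st$n[i])
        stack[[length(stack) + 1L]] <-
          list(i = st$right[i], w = w * st$n[st$right[i]] / st$n[i])
      }
    }
    total
  }
  p <- length(features)
  phi <- setNames(numeric(p), features)
  for (f in features) {
    others <- setdiff(features, f)
    for (k in 0:length(others)) {
      subsets <- if (k == 0) list(character(0))
      else apply(combn(others, k), 2, identity, simplify = FALSE)
      for (S in subsets) {
        w <- factorial(k) * factorial(p - k - 1) / factorial(p)
        phi[f] <- phi[f] + w * (expectation(c(S, f)) - expectation(S))
      }
    }
  }
  phi
}

# Random paired-blob phantom on a small grid: a few spheres per tracer,
# some shared (overlapping) across tracers.
random_blob_phantom <- function(dm = c(20, 20, 20), spacing = c(2, 2, 2),
                                n_shared = 2, n_each = 2) {
  mk <- function() array(0, dm)
  a <- mk(); b <- mk()
  grid_mm <- as.matrix(expand.grid(x = (seq_len(dm[1]) - 1) * spacing[1],
                                   y = (seq_len(dm[2]) - 1) * spacing[2],
                                   z = (seq_len(dm[3]) - 1) * spacing[3]))
  add_sphere <- function(m, ctr, r) {
    d2 <- rowSums(sweep(grid_mm, 2, ctr, "-")^2)
    m[d2 <= r^2] <- 1
    m
  }
  rand_ctr <- function() runif(3, 4, (dm - 3) * spacing)
  for (s in seq_len(n_shared)) {
    ctr <- rand_ctr()
    a <- add_sphere(a, ctr, runif(1, 3, 7))
    b <- add_sphere(b, ctr + runif(3, -3, 3), runif(1, 3, 7))
  }
  for (s in seq_len(n_each)) {
    a <- add_sphere(a, rand_ctr(), runif(1, 2.5, 5))
    b <- add_sphere(b, rand_ctr(), runif(1, 2.5, 5))
  }
  list(a = a, b = b, spacing = spacing)
}

make_vol <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0),
                     units = "SUV") {
  scalar_volume(values, spacing, origin, units = units)
}

make_mask <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  scalar_volume(array(as.numeric(values > 0), dim(values)), spacing, origin,
                units = "binary")
}
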