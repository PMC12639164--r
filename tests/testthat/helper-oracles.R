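# Independent brute-force oracles used to validate the package's metric and
# measurement implementations. These deliberately use plain loops and
# first-principles counting so they share no code path with the package.

# ROC points by explicit threshold enumeration (loops, no ranking).
oracle_roc_points <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  fpr <- 0
  tpr <- 0
  for (c in ths) {
    sel <- scores >= c
    tpr <- c(tpr, sum(labels == 1 & sel) / npos)
    fpr <- c(fpr, sum(labels == 0 & sel) / nneg)
  }
  list(fpr = fpr, tpr = tpr)
}

# Exact pAUC: insert the floor-crossing point on each segment by linear
# interpolation, then trapezoid the clipped curve.
oracle_pauc <- function(scores, labels, floor = 0.8) {
  rc <- oracle_roc_points(scores, labels)
  f <- rc$fpr
  t <- rc$tpr
  area <- 0
  for (i in seq_len(length(f) - 1)) {
    f0 <- f[i]; f1 <- f[i + 1]; t0 <- t[i]; t1 <- t[i + 1]
    if (t1 > floor && t0 < floor && t1 > t0) {
      fm <- f0 + (f1 - f0) * (floor - t0) / (t1 - t0)
      f0 <- fm; t0 <- floor
    }
    h0 <- max(t0 - floor, 0)
    h1 <- max(t1 - floor, 0)
    area <- area + (f1 - f0) * (h0 + h1) / 2
  }
  area
}

# AUC by all-pairs comparison.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# NNT by exhaustive threshold enumeration: among all cutoffs reaching the
# target sensitivity, take the one triaging fewest lesions.
oracle_nnt <- function(scores, labels, target) {
  ths <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  best_n <- Inf
  best_nnt <- NA_real_
  for (c in ths) {
    sel <- scores >= c
    se <- sum(labels == 1 & sel) / npos
    if (se >= target - 1e-12 && sum(sel) < best_n) {
      best_n <- sum(sel)
      best_nnt <- sum(sel) / sum(labels == 1 & sel)
    }
  }
  best_nnt
}

# Top-k sensitivity by direct per-patient enumeration.
oracle_topk <- function(scores, labels, pid, k, mode = "patient") {
  ids <- sprintf("lesion_%09d", seq_along(scores))
  vals <- c()
  for (p in unique(pid[labels == 1])) {
    i <- which(pid == p)
    o <- i[order(-scores[i], ids[i])]
    top <- o[seq_len(min(k, length(o)))]
    if (mode == "patient") {
      vals <- c(vals, any(labels[top] == 1))
    } else {
      vals <- c(vals, sum(labels[top] == 1) / sum(labels[i] == 1))
    }
  }
  mean(vals)
}

# Textbook sRGB (D65) -> CIELAB, coded from the standard formulas.
oracle_srgb_to_lab <- function(rgb) {
  m <- if (is.null(dim(rgb))) matrix(rgb, ncol = 3) else as.matrix(rgb)
  lin <- ifelse(m <= 0.04045, m / 12.92, ((m + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- t(M %*% t(lin))
  wp <- c(0.95047, 1, 1.08883)
  fun <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                            t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- fun(sweep(xyz, 2, wp, "/"))
  cbind(L = 116 * fx[, 2] - 16,
        a = 500 * (fx[, 1] - fx[, 2]),
        b = 200 * (fx[, 2] - fx[, 3]))
}

# Exact polygon area of a rendered blob's generating polar curve.
oracle_blob_area_mm2 <- function(tile) {
  b <- attr(tile, "boundary")
  th <- seq(0, 2 * pi, length.out = 20001)[-1]
  r <- rep(b$R, length(th))
  for (i in seq_along(b$ks)) {
    r <- r + b$R * b$amps[i] * cos(b$ks[i] * th + b$phases[i])
  }
  r <- pmax(r, 0.15 * b$R)
  # polar area, then the anisotropic scaling multiplies area by (1+s)(1-s)
  0.5 * sum(r^2) * diff(th[1:2]) * (1 + b$s_ax) * (1 - b$s_ax)
}

# Independent Moore-neighbour boundary tracer for the perimeter oracle,
# using the same bias-corrected step weights as the definition under test
# but none of its code.
oracle_perimeter_px <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  pts <- which(pad, arr.ind = TRUE)
  start <- pts[order(pts[, 2], pts[, 1])[1], ]  # leftmost-topmost
  # Moore neighbourhood in clockwise order starting from west
  nb <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
              c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  cur <- start
  back <- 1  # came from west
  path <- list(cur)
  repeat {
    found <- FALSE
    for (step in 0:7) {
      k <- ((back + step) %% 8) + 1
      cand <- cur + nb[k, ]
      if (pad[cand[1], cand[2]]) {
        path[[length(path) + 1]] <- cand
        back <- ((k - 1 + 4 + 1) %% 8)  # direction pointing back, advanced
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start) && length(path) > 2) break
    if (length(path) > 8 * (nr * nc)) stop("tracer runaway")
  }
  if (length(path) < 3) return(0)
  per <- 0
  for (i in seq_len(length(path) - 1)) {
    d2 <- sum((path[[i + 1]] - path[[i]])^2)
    per <- per + if (d2 == 1) 0.980 else 1.406
  }
  per
}

# A small synthetic record table with controllable measurement columns, for
# model tests that do not need a full cohort.
make_records <- function(n_patients = 20, lesions_per_patient = 30,
                         prevalence = 0.05, seed = 1) {
  set.seed(seed)
  n <- n_patients * lesions_per_patient
  pid <- rep(sprintf("P%03d", seq_len(n_patients)), each = lesions_per_patient)
  target <- rbinom(n, 1, prevalence)
  rec <- data.frame(
    isic_id = sprintf("L%06d", seq_len(n)),
    patient_id = pid,
    attribution = rep(c("center_a", "center_b"), length.out = n),
    age_approx = sample(seq(20, 90, 5), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    anatom_site_general = sample(tbptriage::anatomic_sites(), n,
                                 replace = TRUE),
    tbp_tile_type = sample(c("cross-polarized", "white"), n, replace = TRUE),
    target = target,
    diagnosis = ifelse(target == 1, "melanoma", "nevus"),
    stringsAsFactors = FALSE
  )
  for (f in tbptriage::measurement_fields()) {
    rec[[paste0("tbp_lv_", f)]] <- rnorm(n) + target * 1.0
  }
  rec
}

disc_mask <- function(r, side = 96) {
  ctr <- (side + 1) / 2
  X <- matrix(seq_len(side), side, side, byrow = TRUE)
  Y <- t(X)
  structure((X - ctr)^2 + (Y - ctr)^2 <= r^2, class = "lesion_mask")
}

circle_traits <- function(d = 6, irr = 0, asym = 0, colorvar = 0,
                          contrast = 0.8, hue = 50) {
  bg_lab <- c(68, 11.5, 16)
  les_lab <- c(68 - (6 + 34 * contrast),
               24 * cos(hue * pi / 180), 24 * sin(hue * pi / 180))
  bg <- tbptriage::lab_to_srgb(bg_lab)
  les <- tbptriage::lab_to_srgb(les_lab)
  list(true_diameter_mm = d,
       lesion_r = les[1], lesion_g = les[2], lesion_b = les[3],
       bg_r = bg[1], bg_g = bg[2], bg_b = bg[3],
       border_irregularity_level = irr, asymmetry_level = asym,
       internal_color_variance_level = colorvar)
}
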