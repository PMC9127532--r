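#' QWPSO configuration
#'
#' Aggregates all parameters of the wormhole-behaved swarm segmentation:
#' swarm dynamics ([qpso_params()]), entanglement thresholds
#' ([cluster_params()]), wormhole geometry ([wormhole_params()]), the
#' foreground polarity, the RNG seed, and whether the wormhole branch is
#' active at all (`wormhole_enabled = FALSE` reduces [qwpso_segment()] exactly
#' to [qpso_segment()]).
#'
#' @param qpso a [qpso_params()].
#' @param cluster a [cluster_params()].
#' @param wormhole a [wormhole_params()].
#' @param polarity `"bright-object"` (clusters brighter than the two-class
#'   threshold over cluster means become foreground) or `"dark-object"`.
#' @param seed integer RNG seed controlling all stochastic behavior.
#' @param wormhole_enabled logical; disable to obtain the QPSO baseline.
#' @return A list of class `"qwpso_config"`.
#' @export
qwpso_config <- function(qpso = qpso_params(), cluster = cluster_params(),
                         wormhole = wormhole_params(),
                         polarity = c("bright-object", "dark-object"),
                         seed = 1L, wormhole_enabled = TRUE) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(qpso, "qpso_params"), inherits(cluster, "cluster_params"),
            inherits(wormhole, "wormhole_params"))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  structure(list(qpso = qpso, cluster = cluster, wormhole = wormhole,
                 polarity = polarity, seed = as.integer(seed),
                 wormhole_enabled = isTRUE(wormhole_enabled)),
            class = "qwpso_config")
}

#' Pixel-pixel entanglement criterion
#'
#' Two pixel particles are entangled (and so belong in one seed cluster) iff
#' both the gray-similarity and the spatial-proximity conditions hold:
#' `|f_ij - f_kl| <= th_f` and `sqrt((i-k)^2 + (j-l)^2) <= th_o`. Both
#' comparisons are boundary-inclusive.
#'
#' @param p1,p2 0-based `(row, col)` pixel coordinates.
#' @param image a [gray_image()].
#' @param cp a [cluster_params()].
#' @return `TRUE` or `FALSE`.
#' @export
pixels_entangled <- function(p1, p2, image, cp) {
  h <- nrow(image); w <- ncol(image)
  chk <- function(p) {
    if (p[1] < 0 || p[1] >= h || p[2] < 0 || p[2] >= w)
      stop("pixel outside image bounds", call. = FALSE)
  }
  chk(p1); chk(p2)
  f1 <- unclass(image)[p1[1] + 1L, p1[2] + 1L]
  f2 <- unclass(image)[p2[1] + 1L, p2[2] + 1L]
  abs(f1 - f2) <= cp$th_f && sqrt(sum((p1 - p2)^2)) <= cp$th_o
}

#' Pixel-seed absorption criterion
#'
#' A pixel particle is absorbed into an existing seed cluster iff its gray
#' value is within `th_f` of the cluster's running mean and it lies within
#' `th_o` (Euclidean pixels) of the *nearest member pixel* of the cluster, so
#' absorption grows connected regions. On absorption the caller updates the
#' running mean and centroid.
#'
#' @param p 0-based `(row, col)` pixel coordinate.
#' @param cluster a [pixel_cluster()].
#' @param image a [gray_image()].
#' @param cp a [cluster_params()].
#' @return `TRUE` or `FALSE`.
#' @export
pixel_absorbed_by_seed <- function(p, cluster, image, cp) {
  g <- unclass(image)[p[1] + 1L, p[2] + 1L]
  if (abs(g - cluster$mean_gray) > cp$th_f) return(FALSE)
  d2 <- (cluster$members[, 1] - p[1])^2 + (cluster$members[, 2] - p[2])^2
  min(d2) <= cp$th_o^2
}

# shared wormhole-existence test on cluster summaries
worm_test <- function(n_a, n_b, mean_a, mean_b, cent_a, cent_b,
                      h, w, cp, wp, delta_theta) {
  if (n_a < 2L || n_b < 2L) return(FALSE)
  if (abs(mean_a - mean_b) > cp$th_f) return(FALSE)
  if (sqrt(sum((cent_a - cent_b)^2)) <= cp$th_o) return(FALSE)
  ra <- disc_embed_point(cent_a, h, w, wp$disc_radius)$r
  rb <- disc_embed_point(cent_b, h, w, wp$disc_radius)$r
  x <- hyperbolic_path_length(ra, rb, delta_theta, wp$zeta)
  connection_probability(x, wp) >= wp$connect_prob_min
}

#' Wormhole existence test between two seed clusters
#'
#' A wormhole links two clusters iff (1) each has at least two member pixels;
#' (2) their positions are not in the neighborhood (centroid distance
#' `> th_o`) but their gray values are similar (`|mean_a - mean_b| <= th_f`);
#' and (3) the similarity matches the wormhole measure: the connection
#' probability of their hyperbolic path length is at least
#' `connect_prob_min`.
#'
#' @param a,b distinct [pixel_cluster()]s.
#' @param image the [gray_image()] both clusters live in.
#' @param cp a [cluster_params()].
#' @param wp a [wormhole_params()].
#' @return `TRUE` or `FALSE`.
#' @export
wormhole_exists <- function(a, b, image, cp, wp = wormhole_params()) {
  h <- nrow(image); w <- ncol(image)
  dtheta <- if (identical(wp$delta_theta_policy, "fixed")) {
    wp$delta_theta_fixed
  } else {
    angular_separation(disc_embed(a, image, wp$disc_radius),
                       disc_embed(b, image, wp$disc_radius))
  }
  worm_test(nrow(a$members), nrow(b$members), a$mean_gray, b$mean_gray,
            a$centroid, b$centroid, h, w, cp, wp, dtheta)
}

#' Merge two clusters through a wormhole
#'
#' Returns one seed cluster whose member set is the union of the two inputs;
#' the mean gray is the member-weighted mean and the centroid the member
#' mean of coordinates. The lower id is kept.
#'
#' @param a,b [pixel_cluster()]s for which [wormhole_exists()] holds.
#' @return A merged [pixel_cluster()].
#' @export
merge_via_wormhole <- function(a, b) {
  members <- rbind(a$members, b$members)
  na <- nrow(a$members); nb <- nrow(b$members)
  structure(list(
    id        = min(a$id, b$id),
    members   = members,
    mean_gray = (na * a$mean_gray + nb * b$mean_gray) / (na + nb),
    centroid  = (na * a$centroid + nb * b$centroid) / (na + nb),
    kind      = "seed"
  ), class = "pixel_cluster")
}

# sd of the 3x3 neighborhood (clipped at borders) around 0-based (r, c)
local_sd3 <- function(img, r, c) {
  h <- nrow(img); w <- ncol(img)
  rows <- max(0L, r - 1L):min(h - 1L, r + 1L)
  cols <- max(0L, c - 1L):min(w - 1L, c + 1L)
  v <- img[rows + 1L, cols + 1L]
  if (length(v) < 2L) return(0)
  stats::sd(v)
}

# two-class threshold over cluster means, weighted by cluster size
# (between-class variance maximization); returns NA if < 2 distinct means
otsu_cluster_threshold <- function(means, sizes) {
  o <- order(means)
  m <- means[o]; n <- sizes[o]
  um <- unique(m)
  if (length(um) < 2L) return(NA_real_)
  best <- -Inf; thr <- NA_real_
  for (i in seq_len(length(um) - 1L)) {
    cut <- (um[i] + um[i + 1L]) / 2
    lo <- m <= cut
    w0 <- sum(n[lo]); w1 <- sum(n[!lo])
    mu0 <- sum(n[lo] * m[lo]) / w0
    mu1 <- sum(n[!lo] * m[!lo]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; thr <- cut }
  }
  thr
}

#' Segment an image with QWPSO
#'
#' Runs the full quantum-and-wormhole-behaved particle swarm loop. Each sweep
#' visits every particle once; the acting particle "meets" its nearest
#' partner and the meeting type decides the action:
#'
#' * **pixel-pixel** (both at unclustered pixels): if the entanglement
#'   criterion [pixels_entangled()] holds, the two pixels form or extend a
#'   seed cluster; otherwise the particle moves by the QPSO update.
#' * **pixel-seed**: if the absorption criterion [pixel_absorbed_by_seed()]
#'   holds, the pixel joins the cluster and the running mean and centroid are
#'   updated; otherwise the particle moves by the QPSO update.
#' * **seed-seed** (the particle stands on a clustered pixel): with the
#'   wormhole branch enabled, the partner is the nearest other cluster of
#'   similar mean gray (proximity in the hidden similarity metric of the
#'   wormhole geometry); the particle moves by [wormhole_update()] toward
#'   that cluster's centroid and the two clusters merge when
#'   [wormhole_exists()] holds. With the branch disabled the particle falls
#'   through to the QPSO update.
#'
#' Fitness of a particle is `-(|gray under particle - mean of nearest
#' cluster|)`, or minus the local 3x3 intensity standard deviation before any
#' cluster exists; personal and global bests maximize fitness. The loop stops
#' when every pixel is clustered or the sweep budget is exhausted; leftover
#' pixels are then attached in one batch to the cluster minimizing the gray
#' difference (ties broken by centroid distance), after which means and
#' centroids are recomputed. Foreground clusters are selected by a two-class
#' between-class-variance threshold over cluster mean grays under the
#' configured polarity; if all cluster means coincide the foreground is
#' empty.
#'
#' @param image a [gray_image()].
#' @param config a [qwpso_config()].
#' @return A list of class `"segmentation_result"` with fields `labels`
#'   (integer matrix; 0 only if the image could not be clustered at all),
#'   `foreground` (logical matrix), `clusters` (list of [pixel_cluster()]s,
#'   each with an `object` flag), `iterations_used` (sweeps), `rng_seed`,
#'   `threshold` (the cluster-mean cut, possibly `NA`), `log` (admission /
#'   merge event data frame), `delta_theta_log` (all angular separations used
#'   by the wormhole branch), `n_fallback` (pixels attached after the loop),
#'   `method`, and `config`.
#' @export
qwpso_segment <- function(image, config = qwpso_config()) {
  stopifnot(inherits(config, "qwpso_config"))
  img <- unclass(gray_image(unclass(image)))
  h <- nrow(img); w <- ncol(img); npx <- h * w
  qp <- config$qpso; cp <- config$cluster; wp <- config$wormhole
  alpha <- qp$alpha
  L <- if (is.null(qp$L)) 0.1 * max(h, w) else qp$L
  M <- qp$swarm_size
  worm_on <- config$wormhole_enabled

  set.seed(config$seed)

  # particles at seeded-random pixel positions
  pos <- cbind(sample.int(h, M, replace = TRUE) - 1,
               sample.int(w, M, replace = TRUE) - 1)
  pos <- pos * 1.0

  # cluster store (grows); members hold 1-based linear indices into img
  cap <- 256L
  cl_active <- logical(cap); cl_n <- integer(cap)
  cl_sumg <- numeric(cap); cl_sumr <- numeric(cap); cl_sumc <- numeric(cap)
  members <- vector("list", cap)
  K <- 0L
  labels <- matrix(0L, h, w)
  n_unlab <- npx

  grow <- function() {
    cap2 <- cap * 2L
    length(cl_active) <<- cap2; length(cl_n) <<- cap2
    length(cl_sumg) <<- cap2; length(cl_sumr) <<- cap2; length(cl_sumc) <<- cap2
    cl_active[(cap + 1L):cap2] <<- FALSE
    cl_n[(cap + 1L):cap2] <<- 0L
    length(members) <<- cap2
    cap <<- cap2
  }

  # event log accumulators
  ev_step <- integer(0); ev_event <- character(0); ev_cluster <- integer(0)
  ev_row <- integer(0); ev_col <- integer(0)
  ev_row2 <- integer(0); ev_col2 <- integer(0)
  ev_gray <- numeric(0); ev_mean_before <- numeric(0); ev_partner <- integer(0)
  log_event <- function(step, event, cluster, rc, rc2 = c(NA_integer_, NA_integer_),
                        gray = NA_real_, mean_before = NA_real_,
                        partner = NA_integer_) {
    ev_step <<- c(ev_step, step); ev_event <<- c(ev_event, event)
    ev_cluster <<- c(ev_cluster, cluster)
    ev_row <<- c(ev_row, rc[1]); ev_col <<- c(ev_col, rc[2])
    ev_row2 <<- c(ev_row2, rc2[1]); ev_col2 <<- c(ev_col2, rc2[2])
    ev_gray <<- c(ev_gray, gray); ev_mean_before <<- c(ev_mean_before, mean_before)
    ev_partner <<- c(ev_partner, partner)
  }
  dtheta_log <- numeric(0)

  lin <- function(rc) rc[1] + 1L + rc[2] * h

  new_cluster <- function(step, rc1, rc2_or_null) {
    if (K == cap) grow()
    K <<- K + 1L; k <- K
    cl_active[k] <<- TRUE
    i1 <- lin(rc1)
    if (is.null(rc2_or_null) || lin(rc2_or_null) == i1) {
      members[[k]] <<- i1
      cl_n[k] <<- 1L; cl_sumg[k] <<- img[i1]
      cl_sumr[k] <<- rc1[1]; cl_sumc[k] <<- rc1[2]
      labels[i1] <<- k; n_unlab <<- n_unlab - 1L
      log_event(step, "entangle", k, rc1, rc1, gray = img[i1])
    } else {
      i2 <- lin(rc2_or_null)
      members[[k]] <<- c(i1, i2)
      cl_n[k] <<- 2L; cl_sumg[k] <<- img[i1] + img[i2]
      cl_sumr[k] <<- rc1[1] + rc2_or_null[1]
      cl_sumc[k] <<- rc1[2] + rc2_or_null[2]
      labels[i1] <<- k; labels[i2] <<- k; n_unlab <<- n_unlab - 2L
      log_event(step, "entangle", k, rc1, rc2_or_null, gray = img[i1])
    }
    k
  }

  absorb <- function(step, rc, k) {
    i <- lin(rc)
    log_event(step, "absorb", k, rc, gray = img[i],
              mean_before = cl_sumg[k] / cl_n[k])
    members[[k]] <<- c(members[[k]], i)
    cl_n[k] <<- cl_n[k] + 1L
    cl_sumg[k] <<- cl_sumg[k] + img[i]
    cl_sumr[k] <<- cl_sumr[k] + rc[1]; cl_sumc[k] <<- cl_sumc[k] + rc[2]
    labels[i] <<- k; n_unlab <<- n_unlab - 1L
  }

  # Eq (19): gray test against running mean, distance test against the
  # nearest member pixel, found by scanning the th_o window in the label map
  try_absorb <- function(step, rc, k) {
    g <- img[lin(rc)]
    if (abs(g - cl_sumg[k] / cl_n[k]) > cp$th_f) return(FALSE)
    w0 <- floor(cp$th_o)
    rows <- max(0, rc[1] - w0):min(h - 1, rc[1] + w0)
    cols <- max(0, rc[2] - w0):min(w - 1, rc[2] + w0)
    sub <- labels[rows + 1L, cols + 1L, drop = FALSE]
    hit <- which(sub == k, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(FALSE)
    d2 <- (rows[hit[, 1]] - rc[1])^2 + (cols[hit[, 2]] - rc[2])^2
    if (min(d2) > cp$th_o^2) return(FALSE)
    absorb(step, rc, k)
    TRUE
  }

  merge_clusters <- function(step, a, b) {
    tgt <- min(a, b); src <- max(a, b)
    labels[members[[src]]] <<- tgt
    members[[tgt]] <<- c(members[[tgt]], members[[src]])
    cl_n[tgt] <<- cl_n[tgt] + cl_n[src]
    cl_sumg[tgt] <<- cl_sumg[tgt] + cl_sumg[src]
    cl_sumr[tgt] <<- cl_sumr[tgt] + cl_sumr[src]
    cl_sumc[tgt] <<- cl_sumc[tgt] + cl_sumc[src]
    cl_active[src] <<- FALSE
    members[src] <<- list(NULL)
    log_event(step, "merge", tgt, c(NA_integer_, NA_integer_), partner = src)
  }

  qpso_move <- function(i, mbest) {
    phi1 <- stats::runif(2); phi2 <- stats::runif(2)
    s <- phi1 + phi2
    attractor <- ifelse(s > 0, (phi1 * pbest[i, ] + phi2 * gbest) / s, gbest)
    mu <- stats::runif(2)
    mu[mu <= 0] <- .Machine$double.eps
    step <- alpha * abs(mbest - pos[i, ]) * log(1 / mu)
    pos[i, ] <<- clip_pos(ifelse(mu > 0.5, attractor - step, attractor + step), h, w)
  }

  # initial fitness: homogeneous 3x3 neighborhoods make good seed sites
  fit_at <- function(rc) {
    if (K > 0L && any(cl_active[seq_len(K)])) {
      act <- which(cl_active[seq_len(K)])
      cr <- cl_sumr[act] / cl_n[act]; cc <- cl_sumc[act] / cl_n[act]
      d2 <- (cr - rc[1])^2 + (cc - rc[2])^2
      k <- act[which.min(d2)]
      -abs(img[lin(rc)] - cl_sumg[k] / cl_n[k])
    } else {
      -local_sd3(img, rc[1], rc[2])
    }
  }

  pbest <- pos
  pbest_fit <- vapply(seq_len(M), function(i)
    fit_at(clip_round_pos(pos[i, ], h, w)), numeric(1))
  gi <- which.max(pbest_fit)
  gbest <- pbest[gi, ]; gbest_fit <- pbest_fit[gi]

  step_ct <- 0L
  iterations_used <- 0L

  for (t in seq_len(qp$max_iter)) {
    for (i in seq_len(M)) {
      step_ct <- step_ct + 1L
      rc <- clip_round_pos(pos[i, ], h, w)
      lab <- labels[lin(rc)]
      act <- if (K > 0L) which(cl_active[seq_len(K)]) else integer(0)
      mbest <- colMeans(pbest)

      if (lab == 0L) {
        # pixel particle: nearest other particle or cluster centroid
        dp <- (pos[-i, 1, drop = TRUE] - pos[i, 1])^2 +
              (pos[-i, 2, drop = TRUE] - pos[i, 2])^2
        jstar <- which.min(dp)
        j <- (seq_len(M)[-i])[jstar]
        dpe <- dp[jstar]
        dce <- Inf; kstar <- 0L
        if (length(act)) {
          cr <- cl_sumr[act] / cl_n[act]; cc <- cl_sumc[act] / cl_n[act]
          d2 <- (cr - pos[i, 1])^2 + (cc - pos[i, 2])^2
          ks <- which.min(d2); dce <- d2[ks]; kstar <- act[ks]
        }
        handled <- FALSE
        if (dpe <= dce) {
          rcj <- clip_round_pos(pos[j, ], h, w)
          labj <- labels[lin(rcj)]
          if (labj == 0L) {
            f1 <- img[lin(rc)]; f2 <- img[lin(rcj)]
            if (abs(f1 - f2) <= cp$th_f &&
                sum((rc - rcj)^2) <= cp$th_o^2) {
              new_cluster(step_ct, rc, rcj)
              handled <- TRUE
            }
          } else {
            handled <- try_absorb(step_ct, rc, labj)
          }
        }
        # a failed particle meeting still counts as meeting the nearest
        # seed area: try absorption there before falling through to a move
        if (!handled && kstar > 0L) {
          handled <- try_absorb(step_ct, rc, kstar)
        }
        if (!handled) qpso_move(i, mbest)
      } else {
        # seed particle
        moved <- FALSE
        if (worm_on && length(act) > 1L) {
          # partner: the nearest other cluster in the hidden similarity
          # metric (smallest mean-gray difference); ties go to the most
          # distant centroid, since wormholes link long-distance nodes
          others <- act[act != lab]
          dmean <- abs(cl_sumg[others] / cl_n[others] -
                       cl_sumg[lab] / cl_n[lab])
          sim <- others[dmean <= cp$th_f]
          if (length(sim)) {
            ca <- c(cl_sumr[lab], cl_sumc[lab]) / cl_n[lab]
            cr <- cl_sumr[sim] / cl_n[sim]; cc <- cl_sumc[sim] / cl_n[sim]
            d2 <- (cr - ca[1])^2 + (cc - ca[2])^2
            dm <- dmean[dmean <= cp$th_f]
            cand <- which(dm <= min(dm) + 1e-9)
            b <- sim[cand[which.max(d2[cand])]]
            cb <- c(cl_sumr[b], cl_sumc[b]) / cl_n[b]
            dtheta <- if (identical(wp$delta_theta_policy, "fixed")) {
              wp$delta_theta_fixed
            } else {
              angular_separation(disc_embed_point(ca, h, w, wp$disc_radius),
                                 disc_embed_point(cb, h, w, wp$disc_radius))
            }
            dtheta_log <- c(dtheta_log, dtheta)
            term <- (2 / wp$zeta) * abs(mbest - pos[i, ]) * log(dtheta / 2)
            newp <- if (dtheta > 2) cb - term else cb + term
            pos[i, ] <- clip_pos(newp, h, w)
            moved <- TRUE
            if (worm_test(cl_n[lab], cl_n[b],
                          cl_sumg[lab] / cl_n[lab], cl_sumg[b] / cl_n[b],
                          ca, cb, h, w, cp, wp, dtheta)) {
              merge_clusters(step_ct, lab, b)
            }
          }
        }
        if (!moved) qpso_move(i, mbest)
      }

      # fitness bookkeeping
      rc2 <- clip_round_pos(pos[i, ], h, w)
      f <- fit_at(rc2)
      if (f > pbest_fit[i]) {
        pbest_fit[i] <- f; pbest[i, ] <- pos[i, ]
        if (f > gbest_fit) { gbest_fit <- f; gbest <- pos[i, ] }
      }
      if (n_unlab == 0L) break
    }
    iterations_used <- t
    if (n_unlab == 0L) break
  }

  n_fallback <- n_unlab
  act <- if (K > 0L) which(cl_active[seq_len(K)]) else integer(0)

  if (length(act) == 0L) {
    # degenerate: the loop never formed a cluster; group everything
    K <- 1L
    cl_active[1L] <- TRUE
    members[[1L]] <- seq_len(npx)
    cl_n[1L] <- npx; cl_sumg[1L] <- sum(as.numeric(img))
    rows0 <- (seq_len(npx) - 1L) %% h
    cols0 <- (seq_len(npx) - 1L) %/% h
    cl_sumr[1L] <- sum(rows0); cl_sumc[1L] <- sum(cols0)
    labels[] <- 1L
    n_unlab <- 0L
    act <- 1L
  } else if (n_unlab > 0L) {
    # batch attachment of leftover pixels against the loop-final means:
    # minimize the gray difference, tie-break by centroid distance
    idx <- which(labels == 0L)
    g <- as.numeric(img[idx])
    pr <- (idx - 1L) %% h; pc <- (idx - 1L) %/% h
    best_df <- rep(Inf, length(idx)); best_dd <- rep(Inf, length(idx))
    best_k <- rep(0L, length(idx))
    for (k in act) {
      mk <- cl_sumg[k] / cl_n[k]
      ckr <- cl_sumr[k] / cl_n[k]; ckc <- cl_sumc[k] / cl_n[k]
      df <- abs(g - mk)
      dd <- (pr - ckr)^2 + (pc - ckc)^2
      upd <- (df < best_df - 1e-9) |
             (abs(df - best_df) <= 1e-9 & dd < best_dd - 1e-9)
      if (any(upd)) {
        best_df[upd] <- df[upd]; best_dd[upd] <- dd[upd]; best_k[upd] <- k
      }
    }
    labels[idx] <- best_k
    for (k in act) {
      sel <- idx[best_k == k]
      if (length(sel)) {
        members[[k]] <- c(members[[k]], sel)
        cl_n[k] <- cl_n[k] + length(sel)
        cl_sumg[k] <- cl_sumg[k] + sum(as.numeric(img[sel]))
        cl_sumr[k] <- cl_sumr[k] + sum((sel - 1L) %% h)
        cl_sumc[k] <- cl_sumc[k] + sum((sel - 1L) %/% h)
      }
    }
    n_unlab <- 0L
  }

  # consolidation: clusters that jointly satisfy the admission criteria
  # (some member pair within th_o, component means within th_f) are the same
  # region and are merged. Edges are taken greedily by increasing mean
  # difference and re-gated against the running component means, so chains of
  # pairwise-similar fragments cannot bridge distinct intensity classes.
  w0 <- floor(cp$th_o)
  if (w0 >= 1L && length(act) > 1L) {
    pair_a <- integer(0); pair_b <- integer(0)
    for (dr in 0:w0) for (dc in (-w0):w0) {
      if (dr == 0L && dc <= 0L) next
      if (dr * dr + dc * dc > cp$th_o^2) next
      ra <- 1:(h - dr); ca <- max(1, 1 - dc):min(w, w - dc)
      a <- labels[ra, ca, drop = FALSE]
      b <- labels[ra + dr, ca + dc, drop = FALSE]
      sel <- a != b
      if (any(sel)) {
        pair_a <- c(pair_a, pmin(a[sel], b[sel]))
        pair_b <- c(pair_b, pmax(a[sel], b[sel]))
      }
    }
    if (length(pair_a)) {
      pairs <- unique(cbind(pair_a, pair_b))
      dmean <- abs(cl_sumg[pairs[, 1]] / cl_n[pairs[, 1]] -
                   cl_sumg[pairs[, 2]] / cl_n[pairs[, 2]])
      keep <- dmean <= cp$th_f
      pairs <- pairs[keep, , drop = FALSE]; dmean <- dmean[keep]
      o <- order(dmean, pairs[, 1], pairs[, 2])
      parent <- seq_len(K)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      for (e in o) {
        ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
        if (ra == rb) next
        if (abs(cl_sumg[ra] / cl_n[ra] - cl_sumg[rb] / cl_n[rb]) > cp$th_f) next
        tgt <- min(ra, rb); src <- max(ra, rb)
        parent[src] <- tgt
        labels[members[[src]]] <- tgt
        members[[tgt]] <- c(members[[tgt]], members[[src]])
        members[src] <- list(NULL)
        cl_n[tgt] <- cl_n[tgt] + cl_n[src]
        cl_sumg[tgt] <- cl_sumg[tgt] + cl_sumg[src]
        cl_sumr[tgt] <- cl_sumr[tgt] + cl_sumr[src]
        cl_sumc[tgt] <- cl_sumc[tgt] + cl_sumc[src]
        cl_active[src] <- FALSE
        log_event(step_ct, "consolidate", tgt, c(NA_integer_, NA_integer_),
                  partner = src)
      }
      act <- which(cl_active[seq_len(K)])
    }
  }

  # foreground: two-class threshold over cluster mean grays
  means <- cl_sumg[act] / cl_n[act]
  sizes <- cl_n[act]
  thr <- otsu_cluster_threshold(means, sizes)
  object <- if (is.na(thr)) {
    rep(FALSE, length(act))
  } else if (identical(config$polarity, "bright-object")) {
    means > thr
  } else {
    means <= thr
  }
  fg_ids <- act[object]
  foreground <- matrix(labels %in% fg_ids, h, w)

  image_cl <- gray_image(img)
  clusters <- lapply(seq_along(act), function(ii) {
    k <- act[ii]
    m <- members[[k]]
    cl <- pixel_cluster(k, cbind((m - 1L) %% h, (m - 1L) %/% h), image_cl,
                        kind = "seed")
    cl$object <- object[ii]
    cl
  })

  log_df <- data.frame(step = ev_step, event = ev_event, cluster = ev_cluster,
                       row = ev_row, col = ev_col, row2 = ev_row2,
                       col2 = ev_col2, gray = ev_gray,
                       mean_before = ev_mean_before, partner = ev_partner,
                       stringsAsFactors = FALSE)

  structure(list(labels = labels, foreground = foreground, clusters = clusters,
                 iterations_used = iterations_used, rng_seed = config$seed,
                 threshold = thr, log = log_df, delta_theta_log = dtheta_log,
                 n_fallback = n_fallback,
                 method = if (worm_on) "qwpso" else "qpso",
                 config = config),
            class = "segmentation_result")
}
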