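#' Construct a pose track
#'
#' A pose track holds, per video frame, the decoded instances: keypoint
#' coordinates at full resolution, per-keypoint confidences in \[0, 1\],
#' an identity label, and a center location (by default the center
#' keypoint's coordinates).
#'
#' @param frames List (length F >= 1) of per-frame instance lists; each
#'   instance is a list with `keypoints` (`K x 2`), `confidence`
#'   (length-K numeric in \[0, 1\]), `identity` (positive integer) and
#'   optionally `center` (length-2 numeric).
#' @param keypoint_names Optional keypoint labels.
#' @return An object of class `adpt_track`.
#' @export
pose_track <- function(frames, keypoint_names = NULL) {
  stopifnot(length(frames) >= 1L)
  frames <- lapply(frames, function(fr) lapply(fr, function(inst) {
    if (is.null(inst$center)) {
      stop("each instance needs a center; supply it or use track_from_arrays")
    }
    if (any(inst$confidence < 0 | inst$confidence > 1)) {
      stop("confidences must lie in [0, 1]")
    }
    inst
  }))
  structure(list(frames = frames, keypoint_names = keypoint_names),
            class = "adpt_track")
}

#' Build a single-animal track from coordinate / confidence arrays
#'
#' @param coords Numeric array `F x K x 2`.
#' @param confidence Numeric matrix `F x K`; defaults to all 1.
#' @param identity Identity label for every frame.
#' @param center_index Keypoint whose coordinates serve as the center.
#' @return An `adpt_track`.
#' @export
track_from_arrays <- function(coords, confidence = NULL, identity = 1L,
                              center_index = 1L) {
  F <- dim(coords)[1L]; K <- dim(coords)[2L]
  if (is.null(confidence)) confidence <- matrix(1, F, K)
  frames <- lapply(seq_len(F), function(f) {
    kp <- matrix(coords[f, , ], K, 2L)
    list(list(keypoints = kp, confidence = confidence[f, ],
              identity = as.integer(identity), center = kp[center_index, ]))
  })
  pose_track(frames)
}

#' @export
print.adpt_track <- function(x, ...) {
  ni <- lengths(x$frames)
  cat("<adpt_track> ", length(x$frames), " frames, ",
      min(ni), "-", max(ni), " instance(s)/frame\n", sep = "")
  invisible(x)
}

# F x K x 2 coordinates of one identity (default: the lowest present).
track_coords <- function(track, identity = NULL) {
  if (is.array(track)) return(track)
  stopifnot(inherits(track, "adpt_track"))
  sel <- select_identity_instances(track, identity)
  K <- nrow(sel[[1L]]$keypoints)
  arr <- array(NA_real_, c(length(sel), K, 2L))
  for (f in seq_along(sel)) arr[f, , ] <- sel[[f]]$keypoints
  arr
}

track_confidence <- function(track, identity = NULL) {
  if (is.matrix(track)) return(track)
  stopifnot(inherits(track, "adpt_track"))
  sel <- select_identity_instances(track, identity)
  do.call(rbind, lapply(sel, function(i) i$confidence))
}

# F x n_identities x 2 centers; NULL if any frame lacks an identity.
track_centers <- function(track) {
  ids <- sort(unique(unlist(lapply(track$frames, function(fr) {
    vapply(fr, function(i) i$identity, integer(1))
  }))))
  if (!length(ids)) return(NULL)
  F <- length(track$frames)
  arr <- array(NA_real_, c(F, length(ids), 2L))
  for (f in seq_len(F)) {
    for (inst in track$frames[[f]]) {
      j <- match(inst$identity, ids)
      arr[f, j, ] <- inst$center
    }
  }
  if (anyNA(arr)) return(NULL)
  arr
}

select_identity_instances <- function(track, identity = NULL) {
  lapply(track$frames, function(fr) {
    if (!length(fr)) stop("frame without instances; metrics need one instance per frame")
    ids <- vapply(fr, function(i) i$identity, integer(1))
    j <- if (is.null(identity)) which.min(ids) else match(identity, ids)
    if (is.na(j)) stop("identity ", identity, " absent from a frame")
    fr[[j]]
  })
}

#' Temporal identity correction
#'
#' Post hoc relabeling of track identities using motion continuity, in
#' two passes. First, instances of each frame are assigned to the
#' previous frame's instances by minimising the summed center
#' displacement (exact assignment for up to 6 instances, greedy beyond);
#' where the assignment contradicts an instance's raw identity and wins
#' by more than `config$hysteresis` pixels over keeping it, the matched
#' predecessor's identity is propagated. Second, a sliding-window
#' majority vote (`config$smoothing_window` frames) smooths each linked
#' tracklet's label sequence. Coordinates and confidences are never
#' touched; the operation is idempotent.
#'
#' @param track An `adpt_track`.
#' @param config An [adpt_config()].
#' @return The corrected `adpt_track`.
#' @export
temporal_identity_correction <- function(track, config = adpt_config()) {
  frames <- track$frames
  F <- length(frames)
  n_inst <- lengths(frames)
  chain_of <- vector("list", F)   # chain id per instance per frame
  labels <- vector("list", F)     # corrected labels
  next_chain <- 0L
  prev <- NULL                    # list(centers, labels, chains)

  for (f in seq_len(F)) {
    fr <- frames[[f]]
    if (!length(fr)) { chain_of[[f]] <- integer(0); labels[[f]] <- integer(0); next }
    centers <- do.call(rbind, lapply(fr, function(i) i$center))
    raw <- vapply(fr, function(i) i$identity, integer(1))
    if (is.null(prev)) {
      ch <- next_chain + seq_len(nrow(centers)); next_chain <- next_chain + nrow(centers)
      chain_of[[f]] <- ch; labels[[f]] <- raw
      prev <- list(centers = centers, labels = raw, chains = ch)
      next
    }
    cost <- outer(seq_len(nrow(centers)), seq_len(nrow(prev$centers)),
                  Vectorize(function(i, j) sqrt(sum((centers[i, ] - prev$centers[j, ])^2))))
    asg <- solve_assignment(cost)
    lab <- raw
    ch <- integer(nrow(centers))
    for (i in seq_len(nrow(centers))) {
      j <- asg[i]
      if (is.na(j)) { next_chain <- next_chain + 1L; ch[i] <- next_chain; next }
      ch[i] <- prev$chains[j]
      proposed <- prev$labels[j]
      if (proposed != raw[i]) {
        jraw <- match(raw[i], prev$labels)
        d_raw <- if (is.na(jraw)) Inf else cost[i, jraw]
        if (d_raw - cost[i, j] > config$hysteresis) lab[i] <- proposed
      }
    }
    # a frame must not carry duplicate identities: revert weakest relabels
    while (anyDuplicated(lab)) {
      dup <- lab[duplicated(lab)][1L]
      idx <- which(lab == dup)
      changed <- idx[lab[idx] != raw[idx]]
      if (!length(changed)) { lab[idx[-1L]] <- raw[idx[-1L]]; break }
      lab[changed[length(changed)]] <- raw[changed[length(changed)]]
    }
    chain_of[[f]] <- ch; labels[[f]] <- lab
    prev <- list(centers = centers, labels = lab, chains = ch)
  }

  labels <- smooth_chain_labels(labels, chain_of, config$smoothing_window)

  out <- frames
  for (f in seq_len(F)) {
    for (i in seq_along(out[[f]])) out[[f]][[i]]$identity <- labels[[f]][i]
  }
  structure(list(frames = out, keypoint_names = track$keypoint_names),
            class = "adpt_track")
}

# Sliding-window majority vote over each chain's label sequence.
smooth_chain_labels <- function(labels, chain_of, window) {
  half <- window %/% 2L
  F <- length(labels)
  chains <- unlist(chain_of)
  if (!length(chains)) return(labels)
  seq_by_chain <- list()
  for (f in seq_len(F)) {
    for (i in seq_along(chain_of[[f]])) {
      cid <- as.character(chain_of[[f]][i])
      seq_by_chain[[cid]] <- rbind(seq_by_chain[[cid]], c(f, i, labels[[f]][i]))
    }
  }
  out <- labels
  for (cid in names(seq_by_chain)) {
    m <- seq_by_chain[[cid]]
    fs <- m[, 1L]; ls <- m[, 3L]
    for (r in seq_len(nrow(m))) {
      w <- which(fs >= fs[r] - half & fs <= fs[r] + half)
      tab <- table(ls[w])
      best <- as.integer(names(tab)[tab == max(tab)])
      newlab <- if (ls[r] %in% best) ls[r] else best[1L]
      out[[m[r, 1L]]][m[r, 2L]] <- newlab
    }
  }
  # uniqueness within a frame after smoothing: fall back to pre-smoothing
  for (f in seq_len(F)) {
    if (anyDuplicated(out[[f]])) out[[f]] <- labels[[f]]
  }
  out
}

# Min-cost one-to-one assignment of rows to columns of `cost`.
# Exact over permutations for n <= 6, greedy beyond. Returns, per row,
# the matched column (NA when rows > cols leaves it unmatched).
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n <= m && n <= 6L && m <= 6L) {
    perms <- permutations_of(m, n)
    best <- NULL; bestc <- Inf
    for (p in perms) {
      cc <- sum(cost[cbind(seq_len(n), p)])
      if (cc < bestc) { bestc <- cc; best <- p }
    }
    return(best)
  }
  asg <- rep(NA_integer_, n)
  used <- rep(FALSE, m)
  ord <- order(apply(cost, 1L, min))
  for (i in ord) {
    free <- which(!used)
    if (!length(free)) break
    j <- free[which.min(cost[i, free])]
    asg[i] <- j; used[j] <- TRUE
  }
  asg
}

permutations_of <- function(m, n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(chosen, left) {
    if (length(chosen) == n) { out[[length(out) + 1L]] <<- chosen; return() }
    for (j in left) rec(c(chosen, j), setdiff(left, j))
  }
  rec(integer(0), seq_len(m))
  out
}

#' Write / read a track as a DeepLabCut-style CSV
#'
#' Multi-index columns scorer / individuals / bodyparts / coords with
#' x, y, likelihood triplets per (individual, bodypart).
#'
#' @param track An `adpt_track`.
#' @param path CSV path.
#' @param keypoint_names Bodypart labels; defaults to `kp1..kpK`.
#' @param scorer Scorer string stored in the header.
#' @return `read_track` returns an `adpt_track` (centers are the first
#'   keypoint unless `center_index` says otherwise).
#' @export
write_track <- function(track, path, keypoint_names = NULL, scorer = "adpt") {
  ids <- sort(unique(unlist(lapply(track$frames, function(fr) {
    vapply(fr, function(i) i$identity, integer(1))
  }))))
  K <- nrow(track$frames[[which(lengths(track$frames) > 0)[1L]]][[1L]]$keypoints)
  kn <- keypoint_names %||% track$keypoint_names %||% paste0("kp", seq_len(K))
  hdr_ind <- character(0); hdr_bp <- character(0); hdr_co <- character(0)
  for (id in ids) for (k in seq_len(K)) {
    hdr_ind <- c(hdr_ind, rep(paste0("individual", id), 3L))
    hdr_bp <- c(hdr_bp, rep(kn[k], 3L))
    hdr_co <- c(hdr_co, c("x", "y", "likelihood"))
  }
  rows <- matrix(NA_real_, length(track$frames), length(hdr_co))
  for (f in seq_along(track$frames)) {
    for (inst in track$frames[[f]]) {
      base <- (match(inst$identity, ids) - 1L) * 3L * K
      for (k in seq_len(K)) {
        rows[f, base + 3L * (k - 1L) + 1:3] <-
          c(inst$keypoints[k, ], inst$confidence[k])
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("scorer", rep(scorer, length(hdr_co))), collapse = ","), con)
  writeLines(paste(c("individuals", hdr_ind), collapse = ","), con)
  writeLines(paste(c("bodyparts", hdr_bp), collapse = ","), con)
  writeLines(paste(c("coords", hdr_co), collapse = ","), con)
  for (f in seq_along(track$frames)) {
    writeLines(paste(c(f - 1L, format(rows[f, ], digits = 17, trim = TRUE)),
                     collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_track
#' @param center_index Keypoint used as center when reading.
#' @export
read_track <- function(path, center_index = 1L) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  labels <- raw[[1L]]
  ind <- as.character(raw[which(labels == "individuals")[1L], -1L])
  bp <- as.character(raw[which(labels == "bodyparts")[1L], -1L])
  co <- as.character(raw[which(labels == "coords")[1L], -1L])
  dat <- raw[-(which(labels %in% c("scorer", "individuals", "bodyparts", "coords"))), -1L,
             drop = FALSE]
  kn <- unique(bp)
  K <- length(kn)
  frames <- vector("list", nrow(dat))
  for (f in seq_len(nrow(dat))) {
    vals <- suppressWarnings(as.numeric(dat[f, ]))
    insts <- list()
    for (id_name in unique(ind)) {
      kp <- matrix(NA_real_, K, 2L); conf <- rep(NA_real_, K)
      for (j in seq_along(ind)) {
        if (ind[j] != id_name) next
        k <- match(bp[j], kn)
        if (co[j] == "x") kp[k, 1L] <- vals[j]
        if (co[j] == "y") kp[k, 2L] <- vals[j]
        if (co[j] == "likelihood") conf[k] <- vals[j]
      }
      if (!all(is.na(kp))) {
        insts[[length(insts) + 1L]] <- list(
          keypoints = kp, confidence = conf,
          identity = match(id_name, unique(ind)),
          center = kp[center_index, ])
      }
    }
    frames[[f]] <- insts
  }
  pose_track(frames, keypoint_names = kn)
}
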