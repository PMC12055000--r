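#' Read a labeled keypoint dataset
#'
#' Reads a dataset directory in either the native layout (an `images/`
#' directory, an `annotations.csv` table in long form, and optionally a
#' `skeleton.yaml`) or a DeepLabCut-style layout (images plus one
#' multi-index CSV with scorer / \[individuals\] / bodyparts / coords
#' header rows). Unannotated cells (`NA`) yield visibility 0, never a
#' coordinate of (0, 0).
#'
#' @param path Dataset directory.
#' @param config An [adpt_config()] (reserved for layout options).
#' @param skeleton An `adpt_skeleton`; if `NULL`, read from
#'   `skeleton.yaml` in `path`. The table's bodypart set must match the
#'   skeleton exactly.
#' @return A list of `adpt_frame` objects, in table order.
#' @export
read_labeled_dataset <- function(path, config = adpt_config(), skeleton = NULL) {
  stopifnot(dir.exists(path))
  if (is.null(skeleton)) {
    skf <- file.path(path, "skeleton.yaml")
    if (!file.exists(skf)) stop("no skeleton given and no skeleton.yaml in ", path)
    skeleton <- read_skeleton(skf)
  }
  native <- file.path(path, "annotations.csv")
  if (file.exists(native)) {
    return(read_native_dataset(path, native, skeleton))
  }
  csvs <- setdiff(list.files(path, pattern = "\\.csv$", full.names = TRUE), native)
  if (length(csvs) == 0L) stop("no annotation table found in ", path)
  read_dlc_dataset(path, csvs[[1L]], skeleton)
}

read_native_dataset <- function(path, table_path, skeleton) {
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  need <- c("frame", "identity", "bodypart", "x", "y", "visible")
  if (!all(need %in% names(tab))) {
    stop("native annotations.csv must have columns: ", paste(need, collapse = ", "))
  }
  bps <- unique(tab$bodypart)
  if (!setequal(bps, skeleton$names)) {
    stop("bodypart set in table {", paste(sort(bps), collapse = ","),
         "} does not match skeleton {", paste(sort(skeleton$names), collapse = ","), "}")
  }
  K <- n_keypoints(skeleton)
  frames <- list()
  for (fname in unique(tab$frame)) {
    ipath <- file.path(path, fname)
    if (!file.exists(ipath)) {
      stop("missing image file '", fname, "' referenced by annotations.csv")
    }
    img <- read_image(ipath)
    sub <- tab[tab$frame == fname, , drop = FALSE]
    insts <- lapply(sort(unique(sub$identity)), function(id) {
      rows <- sub[sub$identity == id, , drop = FALSE]
      kp <- matrix(0, K, 2L); v <- rep(FALSE, K)
      idx <- match(rows$bodypart, skeleton$names)
      kp[idx, 1L] <- rows$x; kp[idx, 2L] <- rows$y
      v[idx] <- as.logical(rows$visible)
      pose_instance(kp, v, identity = id)
    })
    frames[[length(frames) + 1L]] <- labeled_frame(img, insts)
  }
  frames
}

# DeepLabCut-style multi-index CSV: header rows scorer / [individuals] /
# bodyparts / coords, first column holds the image path. NaN = unannotated.
read_dlc_dataset <- function(path, table_path, skeleton) {
  raw <- utils::read.csv(table_path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  labels <- raw[[1L]]
  hdr_rows <- which(labels %in% c("scorer", "individuals", "bodyparts", "coords"))
  if (length(hdr_rows) < 3L) stop("not a DeepLabCut-style table: ", table_path)
  get_row <- function(nm) {
    i <- which(labels == nm)
    if (length(i)) as.character(raw[i[1L], -1L]) else NULL
  }
  bodyparts <- get_row("bodyparts")
  coords <- get_row("coords")
  individuals <- get_row("individuals")
  if (is.null(individuals)) individuals <- rep("animal1", length(bodyparts))
  data_rows <- raw[-hdr_rows, , drop = FALSE]
  bps <- unique(bodyparts)
  if (!setequal(bps, skeleton$names)) {
    stop("bodypart set in table {", paste(sort(bps), collapse = ","),
         "} does not match skeleton {", paste(sort(skeleton$names), collapse = ","), "}")
  }
  K <- n_keypoints(skeleton)
  frames <- vector("list", nrow(data_rows))
  for (r in seq_len(nrow(data_rows))) {
    fname <- data_rows[r, 1L]
    ipath <- file.path(path, fname)
    if (!file.exists(ipath)) {
      stop("missing image file '", fname, "' referenced by table row ", r)
    }
    img <- read_image(ipath)
    vals <- suppressWarnings(as.numeric(data_rows[r, -1L]))
    insts <- list()
    for (id_name in unique(individuals)) {
      kp <- matrix(NA_real_, K, 2L)
      for (j in seq_along(bodyparts)) {
        if (individuals[j] != id_name) next
        k <- match(bodyparts[j], skeleton$names)
        if (coords[j] == "x") kp[k, 1L] <- vals[j]
        if (coords[j] == "y") kp[k, 2L] <- vals[j]
      }
      v <- !(is.na(kp[, 1L]) | is.na(kp[, 2L]))
      if (any(v)) {
        insts[[length(insts) + 1L]] <-
          pose_instance(kp, v, identity = match(id_name, unique(individuals)))
      }
    }
    frames[[r]] <- labeled_frame(img, insts)
  }
  frames
}

#' Write a labeled dataset in the native layout
#'
#' Emits `images/frame_NNNN.png`, a long-form `annotations.csv`
#' (frame, identity, bodypart, x, y, visible) and `skeleton.yaml`.
#' Coordinates round-trip losslessly through [read_labeled_dataset()].
#'
#' @param frames List of `adpt_frame` objects.
#' @param path Output directory (created if needed).
#' @param skeleton An `adpt_skeleton`.
#' @return `path`, invisibly.
#' @export
write_labeled_dataset <- function(frames, path, skeleton) {
  dir.create(file.path(path, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (f in seq_along(frames)) {
    fname <- sprintf("images/frame_%04d.png", f)
    write_image(frames[[f]]$image, file.path(path, fname))
    for (inst in frames[[f]]$instances) {
      for (k in seq_len(nrow(inst$keypoints))) {
        rows[[length(rows) + 1L]] <- data.frame(
          frame = fname, identity = inst$identity,
          bodypart = skeleton$names[k],
          x = inst$keypoints[k, 1L], y = inst$keypoints[k, 2L],
          visible = as.integer(inst$visibility[k])
        )
      }
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(path, "annotations.csv"), row.names = FALSE)
  write_skeleton(skeleton, file.path(path, "skeleton.yaml"))
  invisible(path)
}

#' Convert a DeepLabCut-style dataset to the native layout
#'
#' @param path Directory holding the DeepLabCut-style CSV and its images.
#' @param out Output directory for the native layout.
#' @param skeleton An `adpt_skeleton` naming the expected bodyparts.
#' @return `out`, invisibly.
#' @export
convert_dlc_dataset <- function(path, out, skeleton) {
  frames <- read_labeled_dataset(path, skeleton = skeleton)
  write_labeled_dataset(frames, out, skeleton)
}
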