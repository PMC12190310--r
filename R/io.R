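# NIfTI read/write, subject manifests, and the stratified
# train/validation/test split: 30% of subjects to test, then 30% of the
# remaining 70% to validation (so fractions 0.30 / 0.21 / 0.49).

MANIFEST_COLUMNS <- c("subject_id", "mri_path", "pet_path", "label", "domain")

#' Write a dataset to NIfTI files plus a manifest
#'
#' Writes `<subject_id>_mri.nii.gz` / `<subject_id>_pet.nii.gz` per
#' subject and a `manifest.csv` with header
#' `subject_id,mri_path,pet_path,label,domain` (paths relative to the
#' manifest). Held-out labels (target domain) are written empty in the
#' manifest; for synthetic data the ground truth is additionally saved to
#' `target_labels.csv` so downstream evaluation can score target
#' predictions.
#'
#' @param samples A list of subject samples.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    mf <- paste0(s$subject_id, "_mri.nii.gz")
    pf <- paste0(s$subject_id, "_pet.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(s$mri), file.path(dir, mf))
    RNifti::writeNifti(RNifti::asNifti(s$pet), file.path(dir, pf))
    held <- isTRUE(s$label_held_out)
    data.frame(subject_id = s$subject_id, mri_path = mf, pet_path = pf,
               label = if (held || is.null(s$label)) "" else s$label,
               domain = s$domain, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  held <- Filter(function(s) isTRUE(s$label_held_out) && !is.null(s$label),
                 samples)
  if (length(held)) {
    ht <- data.frame(subject_id = vapply(held, `[[`, "", "subject_id"),
                     label = vapply(held, function(s) as.integer(s$label), 1L))
    write.csv(ht, file.path(dir, "target_labels.csv"), row.names = FALSE,
              quote = FALSE)
  }
  invisible(mpath)
}

#' Read a subject manifest
#'
#' @param path Path to a manifest CSV with the exact header
#'   `subject_id,mri_path,pet_path,label,domain`.
#' @return A data frame of class `mmdda_manifest`; relative image paths
#'   are resolved against the manifest's directory. Missing labels become
#'   `NA`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_mmdda(sprintf("manifest not found: %s", path), "mmdda_io_error")
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  if (!identical(hdr, MANIFEST_COLUMNS))
    stop_mmdda(sprintf("manifest must have columns %s",
                       paste(MANIFEST_COLUMNS, collapse = ",")),
               "mmdda_io_error")
  m <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(subject_id = "character", label = "character"))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$mri_path <- resolve(m$mri_path)
  m$pet_path <- resolve(m$pet_path)
  m$label <- suppressWarnings(as.integer(m$label))
  for (dom in unique(m$domain)) {
    ids <- m$subject_id[m$domain == dom]
    if (anyDuplicated(ids))
      stop_mmdda(sprintf("duplicate subject_id within domain '%s'", dom),
                 "mmdda_io_error")
  }
  if (any(m$domain == "source" & is.na(m$label)))
    stop_mmdda("all source-domain rows must carry a label", "mmdda_io_error")
  class(m) <- c("mmdda_manifest", class(m))
  m
}

#' Load one subject's volume pair
#'
#' Reads the MRI and PET NIfTI files of a manifest row and enforces the
#' co-registration contract: both volumes must live on the same voxel
#' grid.
#'
#' @param row A single manifest row (data frame or named list).
#' @return A subject sample list (`subject_id`, `mri`, `pet`, `label`
#'   possibly `NA`, `domain`).
#' @export
load_sample <- function(row) {
  if (is.data.frame(row)) row <- as.list(row[1, ])
  for (p in c(row$mri_path, row$pet_path))
    if (!file.exists(p))
      stop_mmdda(sprintf("cannot read volume: %s", p), "mmdda_io_error")
  mri <- array(as.numeric(RNifti::readNifti(row$mri_path)),
               dim = dim(RNifti::readNifti(row$mri_path)))
  pet <- array(as.numeric(RNifti::readNifti(row$pet_path)),
               dim = dim(RNifti::readNifti(row$pet_path)))
  if (!identical(dim(mri), dim(pet)))
    stop_mmdda(sprintf(
      "co-registration error: MRI grid (%s) differs from PET grid (%s) for subject %s",
      paste(dim(mri), collapse = "x"), paste(dim(pet), collapse = "x"),
      row$subject_id), "mmdda_coregistration_error")
  lab <- row$label
  lab <- if (is.null(lab) || is.na(lab)) NA_integer_ else as.integer(lab)
  list(subject_id = row$subject_id, mri = mri, pet = pet, label = lab,
       domain = row$domain, label_held_out = FALSE)
}

#' Load every sample of a manifest
#'
#' @param manifest A manifest data frame from [read_manifest()].
#' @return A list of subject samples.
#' @export
load_manifest_samples <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) load_sample(manifest[i, ]))
}

#' Stratified train/validation/test split
#'
#' Assigns `round(0.30 n)` subjects to test, then `round(0.30 (n - test))`
#' to validation, the remainder to train, stratified by label (labelled
#' subjects per class; unlabelled subjects form their own stratum). The
#' split depends only on the manifest and the seed.
#'
#' @param manifest A manifest data frame (needs `subject_id` and `label`).
#' @param seed Integer seed.
#' @return A data frame of class `mmdda_split` mapping `subject_id` to
#'   `split` in `{train, val, test}`.
#' @export
make_split <- function(manifest, seed = 1L) {
  n <- nrow(manifest)
  if (sum(!is.na(manifest$label)) < 10)
    stop_mmdda("make_split needs at least 10 labelled samples", "mmdda_config_error")
  strata <- ifelse(is.na(manifest$label), "unlabelled",
                   paste0("class", manifest$label))
  # global counts: test = round(0.30 n), val = round(0.30 (n - test));
  # strata receive shares by largest remainder so the totals are exact
  n_test <- round(0.30 * n)
  n_val <- round(0.30 * (n - n_test))
  alloc <- function(total, sizes) {
    if (total == 0) return(integer(length(sizes)))
    q <- total * sizes / sum(sizes)
    base <- floor(q)
    rem <- as.integer(total - sum(base))
    if (rem > 0) {
      extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    as.integer(base)
  }
  sts <- unique(strata)
  sizes <- vapply(sts, function(s) sum(strata == s), 1L)
  t_counts <- alloc(n_test, sizes)
  v_counts <- alloc(n_val, sizes - t_counts)
  assign <- character(n)
  withr::with_seed(as.integer(seed), {
    for (k in seq_along(sts)) {
      idx <- which(strata == sts[k])
      idx <- idx[sample.int(length(idx))]
      assign[idx[seq_len2(t_counts[k])]] <- "test"
      assign[idx[t_counts[k] + seq_len2(v_counts[k])]] <- "val"
      rest <- setdiff(seq_along(idx), seq_len(t_counts[k] + v_counts[k]))
      assign[idx[rest]] <- "train"
    }
  })
  labelled <- unique(strata[strata != "unlabelled"])
  if (length(labelled) > 1) {
    for (part in c("train", "val", "test")) {
      present <- unique(strata[assign == part & strata != "unlabelled"])
      if (!setequal(present, labelled))
        stop_mmdda(sprintf(
          "stratification error: a class is absent from the '%s' partition", part),
          "mmdda_stratification_error")
    }
  }
  structure(data.frame(subject_id = manifest$subject_id, split = assign,
                       stringsAsFactors = FALSE),
            class = c("mmdda_split", "data.frame"))
}
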