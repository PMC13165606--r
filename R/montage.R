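#' The standard 19-channel 10-20 montage
#'
#' Returns the electrode montage used throughout the package: the 19 scalp
#' positions of the international 10-20 system (legacy temporal naming
#' T3/T4/T5/T6), ordered front to back, left before right, with the midline
#' channels Fz, Cz and Pz included.
#'
#' @param sampling_rate Sampling rate in Hz (default 256).
#' @return An object of class `eeg_montage`: a list with `channel_names`
#'   (character vector of length 19) and `sampling_rate`.
#' @examples
#' m <- standard_1020_montage()
#' m$channel_names
#' @export
standard_1020_montage <- function(sampling_rate = 256) {
  channels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "T3", "C3", "Cz", "C4", "T4",
                "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  structure(list(channel_names = channels, sampling_rate = sampling_rate),
            class = "eeg_montage")
}

# canonical name -> accepted aliases (case handled separately)
.channel_aliases <- c(
  "T7" = "T3", "T8" = "T4", "P7" = "T5", "P8" = "T6"
)

#' Normalize EEG channel labels
#'
#' Maps channel labels onto the montage's canonical names: matching is
#' case-insensitive and the modern temporal labels T7/T8/P7/P8 are accepted as
#' aliases of T3/T4/T5/T6. Labels that do not resolve are returned unchanged
#' (callers that require resolution use [channel_indices()]).
#'
#' @param labels Character vector of channel labels.
#' @return Character vector of canonical labels, same length as `labels`.
#' @examples
#' normalize_channels(c("FP1", "P7", "cz"))
#' @export
normalize_channels <- function(labels) {
  canon <- standard_1020_montage()$channel_names
  out <- vapply(labels, function(lab) {
    hit <- match(toupper(lab), toupper(canon))
    if (!is.na(hit)) return(canon[hit])
    ali <- match(toupper(lab), toupper(names(.channel_aliases)))
    if (!is.na(ali)) return(unname(.channel_aliases[ali]))
    lab
  }, character(1), USE.NAMES = FALSE)
  out
}

.midline <- c("Fz", "Cz", "Pz")

.hemi_left  <- c("Fp1", "F7", "F3", "Fz", "T3", "C3", "Cz", "T5", "P3", "Pz", "O1")
.hemi_right <- c("Fp2", "F8", "F4", "Fz", "T4", "C4", "Cz", "T6", "P4", "Pz", "O2")
.anterior   <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz", "C4", "T4")
.posterior  <- c("T5", "P3", "Pz", "P4", "T6", "O1", "O2", "Cz")

#' Partition a montage into region subgraphs
#'
#' Assigns electrodes to named brain regions. The default `two_region`
#' strategy splits the montage into left and right hemispheres of 11 channels
#' each, with the midline channels Fz, Cz and Pz shared by both regions so the
#' hemispheric boundary is represented on both sides. `ap` splits at the
#' central line into anterior and posterior groups sharing Cz; `four_region`
#' crosses the two splits; `full_brain` keeps all 19 channels in one region.
#'
#' @param montage An `eeg_montage`, see [standard_1020_montage()].
#' @param strategy One of `"two_region"`, `"four_region"`, `"ap"`,
#'   `"full_brain"`.
#' @return An object of class `region_partition`: list with `strategy`,
#'   `regions` (named list of ordered electrode-label vectors) and
#'   `shared_channels` (labels belonging to more than one region).
#' @examples
#' p <- build_partition(standard_1020_montage(), "two_region")
#' lengths(p$regions)
#' p$shared_channels
#' @export
build_partition <- function(montage = standard_1020_montage(),
                            strategy = c("two_region", "four_region", "ap",
                                         "full_brain")) {
  strategy <- match.arg(strategy)
  regions <- switch(strategy,
    two_region = list(left = .hemi_left, right = .hemi_right),
    ap = list(anterior = .anterior, posterior = .posterior),
    four_region = list(
      left_anterior  = intersect(.hemi_left,  .anterior),
      right_anterior = intersect(.hemi_right, .anterior),
      left_posterior  = intersect(.hemi_left,  .posterior),
      right_posterior = intersect(.hemi_right, .posterior)
    ),
    full_brain = list(all = montage$channel_names)
  )
  labs <- unlist(regions, use.names = FALSE)
  shared <- sort(unique(labs[duplicated(labs)]))
  missing <- setdiff(normalize_channels(labs), montage$channel_names)
  if (length(missing))
    stop("partition channels not present in montage: ",
         paste(missing, collapse = ", "))
  structure(list(strategy = strategy, regions = regions,
                 shared_channels = shared),
            class = "region_partition")
}

#' Resolve partition electrode labels to montage indices
#'
#' @param partition A `region_partition`.
#' @param montage An `eeg_montage`.
#' @return Named list (one element per region) of integer index vectors into
#'   the montage channel axis, in the partition's electrode order.
#' @examples
#' channel_indices(build_partition(), standard_1020_montage())$left
#' @export
channel_indices <- function(partition, montage = standard_1020_montage()) {
  canon <- normalize_channels(montage$channel_names)
  lapply(partition$regions, function(labs) {
    idx <- match(normalize_channels(labs), canon)
    if (anyNA(idx))
      stop("channel not found in montage: ",
           paste(labs[is.na(idx)], collapse = ", "))
    idx
  })
}

#' Serialize a region partition to YAML
#'
#' @param partition A `region_partition`.
#' @param path Optional file path; if `NULL` the YAML string is returned.
#' @return `path` (invisibly) or a YAML character string.
#' @export
partition_to_yaml <- function(partition, path = NULL) {
  obj <- list(strategy = partition$strategy, regions = partition$regions)
  if (is.null(path)) return(yaml::as.yaml(obj))
  writeLines(yaml::as.yaml(obj), path)
  invisible(path)
}

#' Read a region partition from YAML
#'
#' @param path File path, or a YAML string if `text = TRUE`.
#' @param text Treat `path` as YAML text rather than a file name.
#' @return A `region_partition`.
#' @export
partition_from_yaml <- function(path, text = FALSE) {
  obj <- if (text) yaml::yaml.load(path) else yaml::read_yaml(path)
  regions <- lapply(obj$regions, function(x) as.character(unlist(x)))
  labs <- unlist(regions, use.names = FALSE)
  structure(list(strategy = obj$strategy %||% "custom",
                 regions = regions,
                 shared_channels = sort(unique(labs[duplicated(labs)]))),
            class = "region_partition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.region_partition <- function(x, ...) {
  cat("Region partition (", x$strategy, ")\n", sep = "")
  for (r in names(x$regions))
    cat(sprintf("  %-16s [%2d] %s\n", r, length(x$regions[[r]]),
                paste(x$regions[[r]], collapse = " ")))
  if (length(x$shared_channels))
    cat("  shared:", paste(x$shared_channels, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("EEG montage: ", length(x$channel_names), " channels @ ",
      x$sampling_rate, " Hz\n  ", paste(x$channel_names, collapse = " "),
      "\n", sep = "")
  invisible(x)
}
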