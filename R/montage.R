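## The 31-channel wet-electrode 10-20 montage used throughout: channel
## names in amplifier order plus approximate 2-D scalp coordinates
## (head radius 1, x toward the right ear, y toward the nasion) used for
## spatial falloff of artifacts and for topographic maps.

.montage_table <- function() {
  data.frame(
    name = c("FP1", "FP2", "F7", "F3", "F4", "F8",
             "FC5", "FC3", "FC1", "FC2", "FC4", "FC6",
             "C3", "C1", "Cz", "C2", "C4",
             "CP5", "CP3", "CP1", "CP2", "CP4", "CP6",
             "P3", "P1", "Pz", "P2", "P4",
             "O1", "Oz", "O2"),
    x = c(-0.31, 0.31, -0.81, -0.40, 0.40, 0.81,
          -0.62, -0.39, -0.16, 0.16, 0.39, 0.62,
          -0.50, -0.25, 0.00, 0.25, 0.50,
          -0.62, -0.39, -0.16, 0.16, 0.39, 0.62,
          -0.40, -0.20, 0.00, 0.20, 0.40,
          -0.31, 0.00, 0.31),
    y = c(0.95, 0.95, 0.59, 0.52, 0.52, 0.59,
          0.28, 0.26, 0.25, 0.25, 0.26, 0.28,
          0.00, 0.00, 0.00, 0.00, 0.00,
          -0.28, -0.26, -0.25, -0.25, -0.26, -0.28,
          -0.52, -0.50, -0.50, -0.50, -0.52,
          -0.95, -0.95, -0.95),
    stringsAsFactors = FALSE
  )
}

#' Montage specification
#'
#' Describes the electrode layout of a recording: ordered channel names,
#' sampling rate and approximate 2-D scalp coordinates.  The default is the
#' 31-channel international 10-20 montage at 500 Hz used by the rest of the
#' package.
#'
#' @param channel_names character vector of unique channel labels.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param coords data frame with columns \code{name}, \code{x}, \code{y};
#'   defaults to built-in 10-20 positions for known labels.
#' @return object of class \code{montage_spec}.
#' @export
montage_spec <- function(channel_names = NULL, sampling_rate = 500,
                         coords = NULL) {
  tab <- .montage_table()
  if (is.null(channel_names)) channel_names <- tab$name
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  if (is.null(coords)) {
    idx <- match(channel_names, tab$name)
    if (anyNA(idx))
      stop("no built-in coordinates for channel(s): ",
           paste(channel_names[is.na(idx)], collapse = ", "),
           "; supply `coords`")
    coords <- tab[idx, ]
  }
  structure(list(channel_names = channel_names,
                 sampling_rate = sampling_rate,
                 coords = coords),
            class = "montage_spec")
}

#' The default 31-channel 10-20 montage at 500 Hz
#' @return a \code{montage_spec} with the 31 standard labels FP1..O2.
#' @export
default_montage <- function() montage_spec()

#' @export
print.montage_spec <- function(x, ...) {
  cat("<montage_spec> ", length(x$channel_names), " channels @ ",
      x$sampling_rate, " Hz\n", sep = "")
  cat(" ", paste(x$channel_names, collapse = " "), "\n")
  invisible(x)
}

montage_index <- function(montage, names) {
  idx <- match(names, montage$channel_names)
  if (anyNA(idx))
    stop("channel(s) not in montage: ",
         paste(names[is.na(idx)], collapse = ", "))
  idx
}
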