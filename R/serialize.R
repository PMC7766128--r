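## Model and configuration serialization.  Decoder models go to a single
## JSON document (full-precision numbers, so load(save(x)) reproduces the
## model bit for bit); run configuration uses YAML.

#' Save a decoder model to JSON
#'
#' @param model a \code{decoder_model}; @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_decoder_model <- function(model, path) {
  core <- model$core
  obj <- list(
    format = "gaitBCI-decoder",
    version = 1L,
    pair = core$pair,
    k = core$k,
    fs = model$fs,
    window_samples = model$window_samples,
    shift_samples = model$shift_samples,
    n_channels = model$n_channels,
    training_accuracy = model$training_accuracy,
    bank = list(bands = core$fbcsp$bank$bands,
                order = core$fbcsp$bank$order),
    csp = lapply(core$fbcsp$csp, function(m)
      list(W = m$W, var_ratio = m$var_ratio,
           selected_rows = m$selected_rows, n_channels = m$n_channels)),
    ranking = list(mi = core$ranking$mi, order = core$ranking$order),
    selection = list(indices = core$selection$indices,
                     k = core$selection$k,
                     pair_completion = core$selection$pair_completion),
    svm = list(w = core$svm$w, b = core$svm$b, mu = core$svm$mu,
               sd = core$svm$sd, levels = core$svm$levels,
               cost = core$svm$cost))
  ## 17 significant digits round-trips IEEE doubles bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a decoder model from JSON
#' @param path file written by [save_decoder_model()].
#' @return a \code{decoder_model}.
#' @export
load_decoder_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(o$format, "gaitBCI-decoder"))
    stop("not a decoder model file: ", path)
  num <- function(x) as.numeric(unlist(x))
  chr <- function(x) as.character(unlist(x))
  int <- function(x) as.integer(unlist(x))
  bank <- filter_bank(bands = lapply(o$bank$bands, num),
                      order = o$bank$order)
  csp <- lapply(o$csp, function(m) {
    N <- m$n_channels
    structure(list(W = matrix(num(m$W), nrow = N, byrow = TRUE),
                   var_ratio = num(m$var_ratio),
                   selected_rows = int(m$selected_rows),
                   n_channels = N),
              class = "csp_model")
  })
  fb <- structure(list(bank = bank, csp = csp, pair = chr(o$pair),
                       n_features = 4L * length(bank$bands)),
                  class = "fbcsp_model")
  core <- structure(list(
    fbcsp = fb,
    ranking = structure(list(mi = num(o$ranking$mi),
                             order = int(o$ranking$order)),
                        class = "mi_ranking"),
    selection = structure(list(indices = int(o$selection$indices),
                               k = o$selection$k,
                               pair_completion = o$selection$pair_completion),
                          class = "feature_selection"),
    svm = structure(list(w = num(o$svm$w), b = o$svm$b,
                         mu = num(o$svm$mu), sd = num(o$svm$sd),
                         levels = chr(o$svm$levels),
                         cost = o$svm$cost),
                    class = "linear_svm"),
    pair = chr(o$pair), k = o$k), class = "decoder_core")
  structure(list(core = core, pair = chr(o$pair), fs = o$fs,
                 window_samples = o$window_samples,
                 shift_samples = o$shift_samples,
                 n_channels = o$n_channels,
                 training_accuracy = o$training_accuracy),
            class = "decoder_model")
}

.default_run_config <- function() {
  list(seed = 7,
       montage = list(sampling_rate = 500,
                      channels = default_montage()$channel_names),
       filter_bank = list(bands = list(c(7, 9), c(10, 12), c(13, 15),
                                       c(16, 20), c(21, 25), c(26, 34)),
                          order = 4),
       decoder = list(window_s = 2, shift_s = 0.5, k = 6, pair = "gvn",
                      cost = 1, pair_completion = TRUE),
       teb = list(bandpass = c(2, 15), window_s = 1.6, shift_s = 0.4,
                  min_gap_s = 0.15, refractory_s = 2, threshold_mult = 4),
       fsm = list(capacity = 10, fill = 1, empty = -3,
                  gait_stop_by_teb = TRUE),
       evaluation = list(reps = 100, n_test = 10,
                         fd_offline = 4.60, fd_online = 5.97, n_tasks = 3))
}

.validate_run_config <- function(cfg) {
  need <- c("seed", "montage", "filter_bank", "decoder", "teb", "fsm",
            "evaluation")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("run config missing section(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(cfg$montage$sampling_rate) ||
      cfg$montage$sampling_rate <= 0)
    stop("invalid sampling rate in run config")
  for (b in cfg$filter_bank$bands)
    if (b[1] >= b[2]) stop("invalid band in run config")
  if (cfg$fsm$capacity < 1) stop("invalid buffer capacity in run config")
  cfg
}

#' Load (or create) a run configuration
#'
#' YAML document carrying every tunable of the pipeline; all defaults
#' equal the study protocol values (500 Hz, six-band 7-34 Hz bank, 2 s /
#' 0.5 s windows, 1.6 s / 0.4 s TEB windows, size-10 buffers with 1:3
#' fill/empty).  Validated on load.
#'
#' @param path YAML file, or NULL for the defaults.
#' @return validated config list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) .default_run_config()
  else utils::modifyList(.default_run_config(),
                         yaml::read_yaml(path))
  .validate_run_config(cfg)
}

#' Save a run configuration as YAML
#' @param cfg config list; @param path output path.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(.validate_run_config(cfg), path)
  invisible(path)
}
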