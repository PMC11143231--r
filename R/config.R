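#' Read a key-value model configuration file
#'
#' Parses plain-text configuration of the form `section.key = value`
#' (comments with `#`, blank lines ignored) into a nested list. Numeric
#' values are converted; everything else stays character.
#'
#' @param path Path to the configuration file.
#' @return Nested named list, one element per section.
#' @examples
#' cfg <- tempfile(fileext = ".cfg")
#' writeLines(c("model.variant = I", "synthesis.alpha_m = 33",
#'   "synthesis.gamma_m = 0.23", "synthesis.alpha = 4.5",
#'   "synthesis.gamma = 0.23", "regulation.form = hill",
#'   "regulation.Kd = 40", "regulation.nH = 2"), cfg)
#' circuit_model_from_config(read_circuit_config(cfg))$model
#' @export
read_circuit_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) out[[parts]] <- val
    else out[[parts[1]]][[paste(parts[-1], collapse = ".")]] <- val
  }
  out
}

#' Build a circuit model from a parsed configuration
#'
#' Maps a configuration list (see [read_circuit_config()]) to a
#' [circuit_model()] plus optional initial state. Regulation is given either
#' phenomenologically (`regulation.form = hill` with `Kd`, `nH`) or through
#' binding kinetics (`regulation.mechanism`, `regulation.p`, `regulation.q`,
#' `regulation.epsilon`), which become CRS kinetics for the explicit-promoter
#' variants and an Adair regulation otherwise.
#'
#' @param cfg Nested list from [read_circuit_config()].
#' @return List with `model` and `init` (`NULL` when no `init.*` keys given).
#' @export
circuit_model_from_config <- function(cfg) {
  variant <- cfg$model$variant
  if (is.null(variant)) stop("config is missing `model.variant`")
  syn <- lapply(cfg$synthesis, as.numeric)
  crs_variant <- variant %in% c("IV_full", "IV", "QSS", "V", "DDE_CRS")
  reg <- NULL; crs <- NULL
  rc <- cfg$regulation
  if (!is.null(rc$mechanism)) {
    spec <- cooperativity_spec(rc$mechanism, rc$p, rc$q, rc$epsilon)
    rates <- cooperative_rates(spec)
    if (crs_variant) crs <- rates
    else reg <- adair_regulation(equilibrium_constants(rates))
  } else if (identical(rc$form, "hill")) {
    reg <- hill_regulation(rc$Kd, rc$nH)
  } else if (!is.null(rc)) {
    stop("regulation config needs `form = hill` or a binding mechanism")
  }
  delays <- NULL
  dc <- cfg$delays
  if (!is.null(dc)) {
    delays <- if (!is.null(dc$tau_N)) list(tau_N = dc$tau_N, tau_M = dc$tau_M)
    else if (identical(dc$kind, "discrete")) delay_spec("discrete", lag = dc$lag)
    else delay_spec("erlang", shape = dc$shape, rate = dc$rate)
  }
  model <- circuit_model(variant, synthesis = syn, regulation = reg,
                         crs = crs, delays = delays)
  init <- if (!is.null(cfg$init)) {
    v <- unlist(cfg$init)
    stats::setNames(as.numeric(v), names(v))
  }
  list(model = model, init = init)
}
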