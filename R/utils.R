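#' Derive a child seed from a parent seed
#'
#' Every stochastic component of the package draws its own seed from a single
#' global seed through this splitting rule, so adding a new generator never
#' perturbs the random stream of an existing one. The rule is a fixed affine
#' hash of the parent seed and a component label: each character of the label
#' and a stream index are folded into the seed modulo 2^31 - 1.
#'
#' @param seed integer parent seed.
#' @param label character scalar naming the component (e.g. "cellmap").
#' @param index integer stream index for repeated draws under one label.
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647                       # 2^31 - 1, Mersenne prime
  h <- (as.double(seed) %% m)
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + as.double(index) %% m) %% m
  as.integer(h %% (m - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ki67 <- function(msg, class) {
  stop(structure(class = c(class, "ki67cta_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Provenance block for file writers
#'
#' @param seed integer seed used for the artifact.
#' @param config list; hashed into a short fingerprint.
#' @return named list with seed, config hash and package version.
#' @export
provenance <- function(seed = NA_integer_, config = list()) {
  list(seed = seed,
       config_hash = config_hash(config),
       package = "ki67cta",
       version = as.character(utils::packageVersion("ki67cta")))
}

# Order-stable FNV-1a style hash of a config list, hex string.
config_hash <- function(config) {
  if (length(config) && !is.null(names(config)))
    config <- config[order(names(config))]
  txt <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(txt)) h <- ((bitwXor(as.integer(h %% 2^31), ch)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1))
    stop_ki67(sprintf("'%s' must be a probability in [0, 1]", name),
              "ki67cta_config_error")
  invisible(x)
}
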