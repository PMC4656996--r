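# Table-1 production presets: CTD state, DNA length, RE spacer. The
# container radius follows the DNA length (350 A for 100 bp, 300 A for
# 50 bp).
.presets <- data.frame(
  preset = 1:6,
  ctd = c("un-neutralized", "neutralized", "neutralized", "neutralized",
          "neutralized", "neutralized"),
  dna_bp = c(100, 100, 50, 50, 50, 50),
  spacer = c(0, 0, 0, 1, 2, 10)
)

#' Production simulation presets
#' @param id preset id 1..6.
#' @return list: neutralize_ctd, dna_bp, spacer, container_radius.
#' @export
run_preset <- function(id) {
  if (!id %in% .presets$preset) stop("invalid preset ", id)
  r <- .presets[.presets$preset == id, ]
  list(neutralize_ctd = r$ctd == "neutralized", dna_bp = r$dna_bp,
       spacer = r$spacer,
       container_radius = if (r$dna_bp >= 100) 350 else 300)
}

.default_config <- function() {
  list(temperature = 300, salt = 0.21, gamma = 0.02, dt = 0.1,
       steps = 1e5, stride = 1000, seed = 1,
       neutralize_ctd = FALSE, dna_bp = 100, spacer = 0, re_start = 11,
       container_radius = 350, fix_dna_ends = TRUE,
       topology = NULL, coords = NULL, out_dir = "results")
}

#' Load and validate a run configuration
#'
#' YAML key-value config. A `preset` key (1..6) expands to the production
#' CTD/DNA-length/spacer combination; explicitly set fields win over the
#' preset (with a warning). Unknown keys are an error in strict mode.
#'
#' @param path YAML file.
#' @param strict reject unknown keys (default TRUE).
#' @return list of class `cg_run_config` with a `config_hash` attribute.
#' @export
load_config <- function(path, strict = TRUE) {
  if (!is.character(path) || !nzchar(path) || !file.exists(path))
    stop("config file does not exist: '", path, "'")
  raw <- yaml::read_yaml(path)
  cfg <- .default_config()
  known <- c(names(cfg), "preset")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    msg <- paste("unknown config keys:", paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  if (!is.null(raw$preset)) {
    pre <- run_preset(raw$preset)
    clash <- intersect(names(pre), names(raw))
    if (length(clash))
      warning("explicit fields override preset ", raw$preset, ": ",
              paste(clash, collapse = ", "))
    cfg <- modifyList(cfg, pre)
  }
  cfg <- modifyList(cfg, raw[setdiff(names(raw), "preset")])
  for (k in c("topology", "coords"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("config path does not exist: ", cfg[[k]], " (key ", k, ")")
  stopifnot(cfg$temperature > 0, cfg$salt > 0, cfg$gamma >= 0, cfg$dt > 0)
  attr(cfg, "config_hash") <- config_hash(cfg)
  class(cfg) <- c("cg_run_config", "list")
  cfg
}

#' Stable hash of a configuration (md5 of its canonical YAML)
#' @param cfg config list.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- cfg[order(names(cfg))]
  attributes(plain) <- list(names = names(plain))
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}

#' Start a run log
#' @param cfg config; @param seed seed in use.
#' @return environment-backed logger with `$event(msg)` and `$entries()`.
#' @export
run_log <- function(cfg = NULL, seed = NA) {
  env <- new.env()
  env$rows <- list()
  ver <- as.character(utils::packageVersion("p53cg"))
  add <- function(msg) {
    env$rows[[length(env$rows) + 1]] <- data.frame(
      time = format(Sys.time(), "%Y-%m-%d %H:%M:%S"), event = msg,
      seed = seed,
      config_hash = if (is.null(cfg)) NA_character_ else
        attr(cfg, "config_hash"),
      version = ver)
  }
  add("run log opened")
  list(event = function(msg) { add(msg); invisible(NULL) },
       entries = function() do.call(rbind, env$rows))
}
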