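# Configuration files (YAML mirroring scenario_config field for field),
# result serialization (TSV trajectories, CSV strategy snapshots, JSON
# manifests) and fixture metapopulations for tests and examples.

config_fields <- function() {
  c("scenario", "dims", "life_cycle", "m_j", "init", "play_mode", "xi",
    "lambda", "n_interactions", "kappa", "mistakes", "mistake_sd", "beta",
    "generations", "n_groups", "group_size", "p_max", "mu", "sigma_mut",
    "jump_mu", "final_fraction")
}

#' Save a scenario configuration to YAML
#'
#' @param cfg A [scenario_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  x <- cfg[config_fields()]
  x <- x[!vapply(x, is.null, TRUE)]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Load and validate a scenario configuration from YAML
#'
#' Unknown keys are rejected; all [scenario_config()] invariants are
#' enforced (e.g. a GC configuration with repeated play fails).
#'
#' @param path YAML file path.
#' @return A validated `scenario_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  x <- yaml::read_yaml(path)
  if (!is.list(x) || is.null(x$scenario)) {
    stop("config file must provide at least a `scenario` field", call. = FALSE)
  }
  unknown <- setdiff(names(x), config_fields())
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(scenario_config, x)
}

# 32-bit FNV-1a hash of the canonical YAML serialization of a config.
config_hash <- function(cfg) {
  x <- cfg[config_fields()]
  x <- x[!vapply(x, is.null, TRUE)]
  s <- yaml::as.yaml(x)
  bytes <- utf8ToInt(s)
  h <- 2166136261
  mul32 <- function(a, b) {
    lo <- a %% 65536
    hi <- a %/% 65536
    ((lo * b) %% 4294967296 + ((hi * b) %% 65536) * 65536) %% 4294967296
  }
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b)) +
      (h >= 2147483648) * 2147483648
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Build a fixture metapopulation
#'
#' Presets: `tiny` = 4 groups of 6, `small` = 10 groups of 12 (the desk
#' scale used throughout the tests), `paperscale` = 40 groups of 24 (the
#' reference design).
#'
#' @param preset `"tiny"`, `"small"` or `"paperscale"`.
#' @param dims Strategy dimensionality.
#' @param init Initial condition.
#' @param outgroup Whether to carry outgroup strategies.
#' @return A `metapop`.
#' @export
make_fixture <- function(preset = c("tiny", "small", "paperscale"),
                         dims = 3L, init = "random", outgroup = FALSE) {
  preset <- match.arg(preset)
  shape <- switch(preset,
                  tiny = c(4L, 6L),
                  small = c(10L, 12L),
                  paperscale = c(40L, 24L))
  make_population(shape[1L], shape[2L], dims, init, outgroup)
}

# Full-precision numeric formatting for text serialization.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Write a strategy-population snapshot
#'
#' The snapshot is a CSV with columns `individual_id`, `group_id`, `role`
#' (`ingroup`/`outgroup`), `dims`, `i`, `p1`, `p2`, `p3` (unused parameter
#' columns are `NA`), plus `natal_group` and `payoff`, together with a JSON
#' header (`<path>.json`) recording the generation, the territory layout
#' and the configuration hash when available.
#'
#' @param pop A `metapop`.
#' @param path CSV output path.
#' @param cfg Optional [scenario_config()] whose hash goes into the header.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(pop, path, cfg = NULL) {
  stopifnot(inherits(pop, "metapop"))
  n <- pop_size(pop)
  one_role <- function(M, role) {
    P <- matrix(NA_real_, n, 3L)
    P[, seq_len(pop$dims - 1L)] <- M[, -1L]
    data.frame(individual_id = seq_len(n), group_id = pop$group,
               role = role, dims = pop$dims, i = M[, 1L],
               p1 = P[, 1L], p2 = P[, 2L], p3 = P[, 3L],
               natal_group = pop$natal, payoff = pop$payoff)
  }
  df <- one_role(pop$ingroup, "ingroup")
  if (!is.null(pop$outgroup)) df <- rbind(df, one_role(pop$outgroup, "outgroup"))
  num <- c("i", "p1", "p2", "p3", "payoff")
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  header <- list(generation = pop$generation,
                 n_groups = pop$n_groups, group_size = pop$group_size,
                 dims = pop$dims, territory = pop$territory,
                 config_hash = if (!is.null(cfg)) config_hash(cfg))
  jsonlite::write_json(header[!vapply(header, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a strategy-population snapshot
#'
#' @param path CSV path written by [write_snapshot()].
#' @return A `metapop`.
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("snapshot '%s' does not exist", path), call. = FALSE)
  }
  df <- utils::read.csv(path)
  need <- c("individual_id", "group_id", "role", "dims", "i", "p1")
  if (!all(need %in% names(df))) {
    stop("snapshot file lacks the expected columns", call. = FALSE)
  }
  hpath <- paste0(path, ".json")
  header <- if (file.exists(hpath)) jsonlite::read_json(hpath, simplifyVector = TRUE)
  ing <- df[df$role == "ingroup", ]
  ing <- ing[order(ing$individual_id), ]
  dims <- ing$dims[1L]
  n <- nrow(ing)
  grp <- ing$group_id
  n_groups <- if (!is.null(header)) header$n_groups else max(grp)
  group_size <- if (!is.null(header)) header$group_size else n %/% max(grp)
  if (n != n_groups * group_size) {
    stop("snapshot is truncated or inconsistent with its header", call. = FALSE)
  }
  pcols <- c("i", "p1", "p2", "p3")[seq_len(dims)]
  pop <- structure(list(
    ingroup = unname(as.matrix(ing[pcols])),
    outgroup = NULL,
    payoff = ing$payoff,
    group = grp,
    natal = ing$natal_group,
    territory = if (!is.null(header)) as.integer(header$territory) else seq_len(n_groups),
    dims = as.integer(dims),
    n_groups = as.integer(n_groups),
    group_size = as.integer(group_size),
    generation = if (!is.null(header)) as.integer(header$generation) else 0L
  ), class = "metapop")
  out <- df[df$role == "outgroup", ]
  if (nrow(out)) {
    out <- out[order(out$individual_id), ]
    if (nrow(out) != n) stop("snapshot is truncated: outgroup rows missing",
                             call. = FALSE)
    pop$outgroup <- unname(as.matrix(out[pcols]))
  }
  pop
}

#' Write replicate results to a directory
#'
#' Produces `trajectories.tsv` (replicate, generation, surplus,
#' var_share), `competition_log.tsv`, one snapshot CSV per replicate, the
#' configuration YAML and a JSON manifest (config hash, seeds, file
#' inventory with row counts, package version, timestamp). Floats are
#' serialized at full precision, so a read round-trip is lossless.
#'
#' @param results A `replicate_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "replicate_set") || is.list(results))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- results[[1L]]$config
  T <- length(results[[1L]]$surplus)
  traj <- data.frame(
    replicate = rep(seq_along(results), each = T),
    generation = rep(seq_len(T), length(results)),
    surplus = unlist(lapply(results, `[[`, "surplus"), use.names = FALSE),
    var_share = unlist(lapply(results, `[[`, "var_share"), use.names = FALSE))
  write_tsv(traj, file.path(dir, "trajectories.tsv"))
  logs <- lapply(seq_along(results), function(r) {
    cl <- results[[r]]$competition_log
    if (is.null(cl) || nrow(cl) == 0L) return(NULL)
    cbind(replicate = r, cl)
  })
  logs <- logs[!vapply(logs, is.null, TRUE)]
  comp <- if (length(logs)) do.call(rbind, logs) else
    cbind(replicate = integer(0), empty_competition_log())
  write_tsv(comp, file.path(dir, "competition_log.tsv"))
  snaps <- sprintf("snapshot_%03d.csv", seq_along(results))
  for (r in seq_along(results)) {
    write_snapshot(results[[r]]$snapshot, file.path(dir, snaps[r]), cfg)
  }
  save_config(cfg, file.path(dir, "config.yml"))
  manifest <- list(
    config_hash = config_hash(cfg),
    base_seed = attr(results, "base_seed"),
    seeds = vapply(results, function(r) as.integer(r$seed %||% NA_integer_),
                   integer(1)),
    n_replicates = length(results),
    generations = T,
    files = c("trajectories.tsv", "competition_log.tsv", "config.yml", snaps),
    trajectory_rows = nrow(traj),
    competition_rows = nrow(comp),
    package_version = as.character(utils::packageVersion("coopdyn")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read replicate results from a directory
#'
#' Validates the manifest's file inventory and row counts, so a truncated
#' results directory fails with an explicit error.
#'
#' @param dir Directory written by [write_results()].
#' @return A `replicate_set` (snapshots and trajectories restored; the
#'   competition log re-attached per replicate).
#' @export
read_results <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    stop(sprintf("'%s' has no manifest.json", dir), call. = FALSE)
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  missing <- manifest$files[!file.exists(file.path(dir, manifest$files))]
  if (length(missing)) {
    stop(sprintf("results directory is incomplete; missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cfg <- load_config(file.path(dir, "config.yml"))
  if (config_hash(cfg) != manifest$config_hash) {
    stop("config hash mismatch: results do not belong to this config",
         call. = FALSE)
  }
  traj <- utils::read.delim(file.path(dir, "trajectories.tsv"))
  if (nrow(traj) != manifest$trajectory_rows) {
    stop("trajectories.tsv is truncated", call. = FALSE)
  }
  comp <- utils::read.delim(file.path(dir, "competition_log.tsv"))
  if (nrow(comp) != manifest$competition_rows) {
    stop("competition_log.tsv is truncated", call. = FALSE)
  }
  reps <- lapply(seq_len(manifest$n_replicates), function(r) {
    tr <- traj[traj$replicate == r, ]
    cl <- comp[comp$replicate == r, setdiff(names(comp), "replicate")]
    rownames(cl) <- NULL
    structure(list(
      surplus = tr$surplus,
      var_share = tr$var_share,
      snapshot = read_snapshot(file.path(dir, sprintf("snapshot_%03d.csv", r))),
      competition_log = cl,
      seed = manifest$seeds[r],
      config = cfg
    ), class = "replicate_result")
  })
  structure(reps, class = "replicate_set", base_seed = manifest$base_seed,
            seeds = manifest$seeds)
}
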