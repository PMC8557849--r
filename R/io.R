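#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration (by file extension), rejects unknown
#' keys, validates values, and fills defaults.  Known keys: `N`, `tb`,
#' `f` (fitness vector), `times`, `K`, `draws` (default `1e4`), `nodes`
#' (default 24), `tol` (default `1e-8`), `seed`, `out`, `verbose`
#' (default FALSE).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated named list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  # YAML 1.1 would coerce bare keys like `N` or `y` to booleans; keep
  # boolean-looking scalars as strings and re-coerce known logical values
  # in normalize_config()
  keep <- list("bool#yes" = function(v) v, "bool#no" = function(v) v)
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path, handlers = keep),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("config must be YAML or JSON", call. = FALSE)
  )
  normalize_config(raw)
}

#' @rdname load_config
#' @param cfg A raw named list of configuration values.
#' @export
normalize_config <- function(cfg) {
  known <- c("N", "tb", "f", "times", "K", "draws", "nodes", "tol", "seed",
             "out", "verbose")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(draws = 1e4, nodes = 24, tol = 1e-8, verbose = FALSE)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$verbose <- isTRUE(cfg$verbose) ||
    (is.character(cfg$verbose) &&
       tolower(cfg$verbose) %in% c("true", "yes", "y", "on"))
  if (!is.null(cfg$N) && (cfg$N < 2 || cfg$N != round(cfg$N))) {
    stop("config key `N` must be an integer >= 2", call. = FALSE)
  }
  if (!is.null(cfg$tb) && cfg$tb <= 0) stop("config key `tb` must be > 0", call. = FALSE)
  if (!is.null(cfg$f) && any(cfg$f <= 0)) stop("config key `f` must be > 0", call. = FALSE)
  if (cfg$tol <= 0) stop("config key `tol` must be > 0", call. = FALSE)
  if (is.null(cfg$seed)) {
    cfg$seed <- sample.int(.Machine$integer.max, 1)
    cfg$seed_autogenerated <- TRUE
  }
  cfg <- cfg[c(intersect(known, names(cfg)), setdiff(names(cfg), known))]
  class(cfg) <- "run_config"
  cfg
}

#' @rdname load_config
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  cfg <- unclass(cfg)
  cfg$seed_autogenerated <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

# provenance header written at the top of every TSV the package emits
.provenance_header <- function(seed = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("moranlink")),
                error = function(e) "dev")
  c(
    sprintf("# moranlink %s", v),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    "# time units: 1 unit = 1 expected birth/death event; N units ~ 1 generation"
  )
}

.write_tsv <- function(df, path, seed = NULL, row_label = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = !is.null(row_label),
                     col.names = if (is.null(row_label)) TRUE else NA)
  invisible(path)
}

.read_tsv <- function(path, row_names = FALSE) {
  utils::read.delim(path, comment.char = "#",
                    row.names = if (row_names) 1L else NULL,
                    check.names = FALSE)
}

#' Read and write sitewise fitness tables
#'
#' TSV with one header row naming the 20 amino acids in the canonical
#' order `ACDEFGHIKLMNPQRSTVWY` and one row per site.  Lines starting with
#' `#` are provenance comments.
#'
#' @param path File path.
#' @return `read_fitness_table()`: numeric `M x 20` matrix with amino-acid
#'   column names.
#' @export
read_fitness_table <- function(path) {
  df <- .read_tsv(path, row_names = TRUE)
  m <- as.matrix(df)
  if (!setequal(colnames(m), AMINO_ACIDS)) {
    stop("fitness table header must be the 20 amino acids", call. = FALSE)
  }
  m <- m[, AMINO_ACIDS, drop = FALSE]
  if (any(m <= 0)) stop("fitness table entries must be > 0", call. = FALSE)
  m
}

#' @rdname read_fitness_table
#' @param x Matrix to write.
#' @param seed Seed recorded in the provenance header.
#' @export
write_fitness_table <- function(x, path, seed = NULL) {
  stopifnot(is.matrix(x), ncol(x) == length(AMINO_ACIDS))
  colnames(x) <- AMINO_ACIDS
  if (is.null(rownames(x))) rownames(x) <- paste0("site", seq_len(nrow(x)))
  .write_tsv(as.data.frame(x), path, seed = seed, row_label = "site")
}

#' Read and write 20x20 amino-acid mutation-rate matrices
#'
#' TSV, rows and columns in canonical amino-acid order, zero diagonal.
#' @inheritParams read_fitness_table
#' @return `read_mutation_matrix()`: numeric 20x20 matrix.
#' @export
read_mutation_matrix <- function(path) {
  m <- as.matrix(.read_tsv(path, row_names = TRUE))
  if (!setequal(colnames(m), AMINO_ACIDS)) {
    stop("mutation matrix header must be the 20 amino acids", call. = FALSE)
  }
  m <- m[AMINO_ACIDS, AMINO_ACIDS]
  if (any(m < 0) || any(diag(m) != 0)) {
    stop("mutation rates must be >= 0 with zero diagonal", call. = FALSE)
  }
  m
}

#' @rdname read_mutation_matrix
#' @export
write_mutation_matrix <- function(x, path, seed = NULL) {
  stopifnot(is.matrix(x), all(dim(x) == length(AMINO_ACIDS)))
  dimnames(x) <- list(AMINO_ACIDS, AMINO_ACIDS)
  .write_tsv(as.data.frame(x), path, seed = seed, row_label = "aa")
}

#' Read and write substitution-record tables
#'
#' TSV with columns `branch`, `site`, `from`, `to`, `tb`; one row per
#' substitution, grouped into per-branch [substitution_record()]s on read.
#'
#' @inheritParams read_fitness_table
#' @param N Population size attached to each record on read.
#' @return `read_substitution_records()`: list of `substitution_record`.
#' @export
read_substitution_records <- function(path, N) {
  df <- .read_tsv(path)
  need <- c("branch", "site", "from", "to", "tb")
  if (!all(need %in% names(df))) {
    stop("substitution records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$branch), function(d) {
    substitution_record(d$branch[1], d$site, d$from, d$to, d$tb[1], N)
  })
}

#' @rdname read_substitution_records
#' @param records List of `substitution_record`.
#' @export
write_substitution_records <- function(records, path, seed = NULL) {
  if (inherits(records, "substitution_record")) records <- list(records)
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(branch = r$branch, site = r$site, from = r$from, to = r$to,
               tb = r$tb)
  }))
  .write_tsv(df, path, seed = seed)
}

#' Generate deterministic small fixtures
#'
#' Writes example inputs for the simulators and the likelihood module:
#' \describe{
#'   \item{`"fitness-table"`}{a 5-site x 20-amino-acid table, each site
#'     with one advantageous character (fitness 1.5) against a background
#'     of 1.0;}
#'   \item{`"mutation-matrix"`}{a uniform 20x20 matrix (rate `1e-3` per
#'     ordered pair, zero diagonal);}
#'   \item{`"substitution-records"`}{10 synthetic branch records produced
#'     by running the finite-sites Gillespie simulator on the fixture
#'     fitness table and logging its substitutions.}
#' }
#' Identical seeds give byte-identical files.
#'
#' @param kind One of the fixture kinds above.
#' @param path Output file path.
#' @param seed Integer seed (default 1).
#' @return The path, invisibly.
#' @export
make_fixtures <- function(kind = c("fitness-table", "mutation-matrix",
                                   "substitution-records"),
                          path, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  fit <- matrix(1, nrow = 5, ncol = 20, dimnames = list(NULL, AMINO_ACIDS))
  adv <- sample(seq_len(20), 5)
  for (s in 1:5) fit[s, adv[s]] <- 1.5
  if (kind == "fitness-table") {
    return(invisible(write_fitness_table(fit, path, seed = seed)))
  }
  mu <- matrix(1e-3, 20, 20); diag(mu) <- 0
  if (kind == "mutation-matrix") {
    return(invisible(write_mutation_matrix(mu, path, seed = seed)))
  }
  # substitution records: simulate branches until 10 carry substitutions
  cfg <- finite_sites_config(N = 10, site_fitness = fit, mutation_rate = mu)
  start <- AMINO_ACIDS[apply(fit, 1, function(r) which(r == 1)[1])]
  records <- list()
  b <- 0
  while (length(records) < 10) {
    b <- b + 1
    log <- simulate_finite_sites(cfg, tb = 200, init = start,
                                 record_events = FALSE)
    if (nrow(log$substitutions) >= 1) {
      s <- log$substitutions
      records[[length(records) + 1L]] <- substitution_record(
        branch = sprintf("b%02d", length(records) + 1L),
        site = s$site, from = s$from, to = s$to, tb = 200, N = cfg$N
      )
    }
  }
  invisible(write_substitution_records(records, path, seed = seed))
}
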