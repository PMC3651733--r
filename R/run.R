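#' Bidirectional Bayes factor run with optional split-interval checkpointing
#'
#' High-level driver: traverses the path in the requested direction(s) and
#' reports classic path sampling, mean path sampling and stepping-stone
#' estimates plus the bidirectional summary. When a `checkpoint_dir` is
#' given, each split interval of each direction runs as an independent,
#' individually seeded and equilibrated chain whose per-interval result is
#' written to disk as JSON; re-invoking with the same arguments skips
#' completed intervals, and a resumed run is identical to an uninterrupted
#' one. Without a checkpoint directory, each direction is one continuous
#' traversal and split contributions are decomposed from the single trace.
#'
#' @param pair a model pair.
#' @param schedule annealing `bf_schedule` (the melting traversal reverses
#'   it); give it splits via `n_splits`/[add_splits()] to enable the
#'   bidirectional error decomposition.
#' @param directions `"both"`, `"annealing"` or `"melting"`.
#' @param seed base integer seed; all traversal and interval seeds derive
#'   from it.
#' @param checkpoint_dir optional directory for per-interval checkpoints.
#' @param save_interval,n_equil forwarded to [run_path()].
#' @return List with one `bf_estimate` per method per direction
#'   (`$annealing`, `$melting`, each a list `ps`/`ps_mean`/`ss`) and, when
#'   both directions run, `$bidirectional`.
#' @export
run_bf <- function(pair, schedule, directions = c("both", "annealing",
                                                  "melting"),
                   seed = 1L, checkpoint_dir = NULL, save_interval = 10L,
                   n_equil = NULL) {
  directions <- match.arg(directions)
  dirs <- if (directions == "both") c("annealing", "melting") else directions
  out <- list()
  for (d in dirs) {
    sched <- if (d == "annealing") schedule else reverse_schedule(schedule)
    out[[d]] <- if (is.null(checkpoint_dir))
      run_direction_whole(pair, sched, seed, save_interval, n_equil)
    else
      run_direction_split(pair, sched, seed, checkpoint_dir, save_interval,
                          n_equil)
  }
  if (length(dirs) == 2) {
    out$bidirectional <- list(
      ps = bidirectional_summary(out$annealing$ps, out$melting$ps),
      ps_mean = bidirectional_summary(out$annealing$ps_mean,
                                      out$melting$ps_mean),
      ss = bidirectional_summary(out$annealing$ss, out$melting$ss))
  }
  out
}

run_direction_whole <- function(pair, sched, seed, save_interval, n_equil) {
  trace <- run_path(pair, sched, mode = "ss", n_equil = n_equil,
                    save_interval = save_interval,
                    seed = interval_seed(seed, 0L, sched$direction))
  list(ps = ps_estimate(trace), ps_mean = ps_mean_estimate(trace),
       ss = ss_log_bf(trace))
}

run_direction_split <- function(pair, sched, seed, checkpoint_dir,
                                save_interval, n_equil) {
  dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  edges <- c(0, sched$splits, 1)
  n_int <- length(edges) - 1L
  per <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    ck <- file.path(checkpoint_dir,
                    sprintf("interval_%s_%02d.json", sched$direction, i))
    if (file.exists(ck)) {
      per[[i]] <- jsonlite::read_json(ck, simplifyVector = TRUE)
      next
    }
    sub <- subset_schedule(sched, edges[i], edges[i + 1])
    trace <- run_path(pair, sub, mode = "ss", n_equil = n_equil,
                      save_interval = save_interval,
                      seed = interval_seed(seed, i, sched$direction))
    res <- list(
      lo = edges[i], hi = edges[i + 1],
      ps = sum(segment_terms(trace, "ps")$contribution),
      ps_mean = sum(segment_terms(trace, "ps_mean")$contribution),
      ss = sum(segment_terms(trace, "ss")$contribution),
      ss_variance = tryCatch(ss_variance(trace),
                             error = function(e) NA_real_),
      ps_mean_variance = tryCatch(ps_sampling_variance_trace(trace),
                                  error = function(e) NA_real_),
      sigma_d = discretization_error(trace))
    jsonlite::write_json(res, ck, auto_unbox = TRUE, digits = NA)
    per[[i]] <- res
  }
  assemble <- function(method, variance_field) {
    contrib <- vapply(per, function(x) x[[method]], numeric(1))
    v <- if (is.null(variance_field)) NA_real_
    else sum(vapply(per, function(x) x[[variance_field]] %||% NA_real_,
                    numeric(1)))
    sd_tot <- if (method != "ss")
      sum(vapply(per, function(x) x$sigma_d, numeric(1))) else NA_real_
    e <- new_bf_estimate(sum(contrib), if (method == "ps_mean") "ps_mean"
                         else method, sched$direction, variance = v,
                         discretization_error = sd_tot)
    e$splits <- data.frame(lo = vapply(per, `[[`, numeric(1), "lo"),
                           hi = vapply(per, `[[`, numeric(1), "hi"),
                           contribution = contrib)
    e
  }
  list(ps = assemble("ps", NULL),
       ps_mean = assemble("ps_mean", "ps_mean_variance"),
       ss = assemble("ss", "ss_variance"))
}

#' Execute a full run from a configuration file
#'
#' The configuration (YAML or JSON) names either a toy pair or a data set
#' (FASTA alignment + Newick tree), a schedule, directions and a seed.
#' Results are written as JSON plus a flat one-row-per-estimate CSV.
#'
#' @param config path to a YAML/JSON file, or an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @return The [run_bf()] result, invisibly.
#' @export
run_from_config <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pair <- build_pair_from_config(cfg)
  schedule <- build_schedule_from_config(cfg$schedule %||% list())
  seed <- as.integer(cfg$seed %||% 1L)
  res <- run_bf(pair, schedule,
                directions = cfg$direction %||% "both", seed = seed,
                checkpoint_dir = if (isTRUE(cfg$checkpoint))
                  file.path(out_dir, "checkpoints") else NULL,
                save_interval = as.integer(cfg$save_interval %||% 10L))
  write_bf_results(res, cfg, seed, out_dir)
  invisible(res)
}

#' @rdname run_from_config
#' @param path configuration file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

build_pair_from_config <- function(cfg) {
  if (!is.null(cfg$toy)) {
    t <- cfg$toy
    fam <- t$family %||% "beta_binomial"
    if (fam == "beta_binomial") {
      # accept trials/successes (n/k also work, but a bare `n:` key is a
      # YAML 1.1 boolean, so the long names are the documented ones)
      n <- t$trials %||% t$n
      k <- t$successes %||% t$k
      toy_pair(
        beta_binomial_spec(n, k, t$shape1_0 %||% 1, t$shape2_0 %||% 1),
        beta_binomial_spec(n, k, t$shape1_1 %||% 2, t$shape2_1 %||% 2))
    } else {
      y <- as.numeric(t$y)
      toy_pair(
        conjugate_normal_spec(y, t$sigma0 %||% 1, t$prior_mean %||% 0,
                              t$prior_sd %||% 1),
        conjugate_normal_spec(y, t$sigma1 %||% 1, t$prior_mean %||% 0,
                              t$prior_sd %||% 1))
    }
  } else if (!is.null(cfg$data)) {
    aln <- read_alignment(cfg$data$alignment)
    tr <- read_tree(cfg$data$tree)
    phylo_pair(aln, tr, root_order = cfg$data$root_order %||% 0,
               strand_symmetric = !isFALSE(cfg$data$strand_symmetric),
               priors = prior_config(
                 mu_shape = cfg$priors$mu_shape %||% 2.1,
                 mu_scale = cfg$priors$mu_scale %||% 1.1))
  } else stop("config must define either 'toy' or 'data'")
}

build_schedule_from_config <- function(s) {
  kind <- s$kind %||% "sigmoid"
  K <- as.integer(s$K %||% 50L)
  Q <- as.integer(s$Q %||% 200L)
  sched <- switch(kind,
    constant = constant_schedule(K, Q),
    sigmoid = sigmoid_schedule(K, Q, alpha = s$alpha %||% 10),
    flexible = flexible_schedule(as.numeric(s$boundaries),
                                 as.integer(s$per_interval_K), Q),
    stop("unknown schedule kind: ", kind))
  if (!is.null(s$n_splits)) sched <- add_splits(sched, as.integer(s$n_splits))
  sched
}

write_bf_results <- function(res, cfg, seed, out_dir) {
  flatten <- function(e, direction, method) {
    data.frame(direction = direction, method = method, log_bf = e$log_bf,
               variance = e$variance,
               discretization_error = e$discretization_error,
               bidirectional_error = e$bidirectional_error, seed = seed)
  }
  rows <- list()
  js <- list(seed = seed,
             config_hash = substr(digest_config(cfg), 1, 12))
  for (d in names(res)) {
    js[[d]] <- lapply(res[[d]], function(e) {
      list(log_bf = e$log_bf, variance = e$variance,
           discretization_error = e$discretization_error,
           bidirectional_error = e$bidirectional_error,
           interpretation = interpret_log_bf(e$log_bf),
           splits = e$splits)
    })
    for (m in names(res[[d]]))
      rows[[length(rows) + 1L]] <- flatten(res[[d]][[m]], d, m)
  }
  jsonlite::write_json(js, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(do.call(rbind, rows),
                   file.path(out_dir, "results.csv"), row.names = FALSE)
  invisible(out_dir)
}

# content hash of the configuration for provenance in outputs
digest_config <- function(cfg) {
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  # small polynomial rolling hash; avoids an extra dependency
  h <- 0
  for (b in utf8ToInt(as.character(txt))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
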