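# Configuration files, trace serialization, random test fixtures, and the
# command-line entry point.

CONFIG_SCHEMA_VERSION <- 1L

config_known_keys <- list(
  top = c("schema_version", "payoffs", "esteem", "precision_prior", "game",
          "engine"),
  payoffs = c("wage", "gain", "return_self", "return_other", "fractions"),
  esteem = c("e_prosocial", "e_antisocial", "e_self", "beta_r"),
  precision_prior = c("shape", "scale"),
  game = c("n_rounds", "seed", "other_true_esteem"),
  engine = c("tol", "max_iter", "carry_precision")
)

reject_unknown <- function(x, section) {
  extra <- setdiff(names(x), config_known_keys[[section]])
  if (length(extra)) {
    stop(sprintf("config: unknown key(s) in `%s`: %s",
                 section, paste(extra, collapse = ", ")))
  }
}

#' Load a run configuration
#'
#' Reads a YAML configuration, validates it against the schema, rejects
#' unknown keys, and fills every missing field with the package defaults
#' (wage 20, gain 3, the example return tables, gamma prior shape 8 scale 1,
#' esteem +0.6/-0.1 with self-esteem 0, and a `beta_r` calibrated so no
#' partner-response probability exceeds 0.8).
#'
#' @param path Path to a YAML file; an empty or missing-section file yields
#'   the full default configuration.
#' @return A [trust_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config: top level must be a mapping")
  config_from_list(raw)
}

config_from_list <- function(raw) {
  reject_unknown(raw, "top")
  sv <- raw$schema_version
  if (!is.null(sv) && sv != CONFIG_SCHEMA_VERSION) {
    stop("config: unsupported schema_version ", sv)
  }
  for (sec in c("payoffs", "esteem", "precision_prior", "game", "engine")) {
    if (!is.null(raw[[sec]])) reject_unknown(raw[[sec]], sec)
  }
  p <- raw$payoffs
  as_table <- function(x, name) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) x <- as.matrix(x)
    m <- if (is.matrix(x)) {
      matrix(as.numeric(x), nrow(x), ncol(x))  # rows already outer lists
    } else {
      matrix(as.numeric(unlist(x)), 2, 2, byrow = TRUE)
    }
    if (length(m) != 4 || anyNA(m)) stop("config: `", name, "` must be a 2 x 2 table")
    m
  }
  payoff_args <- list(
    wage = p$wage %||% 20,
    gain = p$gain %||% 3,
    fractions = if (!is.null(p$fractions)) {
      list(f_self = as.numeric(unlist(p$fractions$f_self)),
           f_other = as.numeric(unlist(p$fractions$f_other)))
    }
  )
  rs <- as_table(p$return_self, "return_self")
  ro <- as_table(p$return_other, "return_other")
  if (!is.null(rs)) payoff_args$return_self <- rs
  if (!is.null(ro)) payoff_args$return_other <- ro
  payoffs <- do.call(payoff_config, payoff_args)

  e <- raw$esteem
  esteem <- esteem_config(
    e_prosocial = e$e_prosocial %||% 0.6,
    e_antisocial = e$e_antisocial %||% -0.1,
    e_self = e$e_self %||% 0,
    beta_r = e$beta_r,
    payoffs = payoffs
  )
  pp <- raw$precision_prior
  g <- raw$game
  en <- raw$engine
  if (!is.null(g$n_rounds) && (!is.numeric(g$n_rounds) || g$n_rounds < 1)) {
    stop("config: `n_rounds` must be a count >= 1")
  }
  trust_config(
    payoffs = payoffs, esteem = esteem,
    precision_prior = list(shape = pp$shape %||% 8, scale = pp$scale %||% 1),
    n_rounds = g$n_rounds %||% 32,
    seed = g$seed %||% 1,
    other_true_esteem = g$other_true_esteem %||% "n",
    carry_precision = en$carry_precision %||% TRUE,
    tol = en$tol %||% 1e-6,
    max_iter = en$max_iter %||% 64
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a configuration as YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param cfg A [trust_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "trust_config"))
  out <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    payoffs = list(
      wage = cfg$payoffs$wage, gain = cfg$payoffs$gain,
      return_self = unname(apply(cfg$payoffs$return_self, 1, as.list, simplify = FALSE)),
      return_other = unname(apply(cfg$payoffs$return_other, 1, as.list, simplify = FALSE))
    ),
    esteem = list(
      e_prosocial = cfg$esteem$e_prosocial,
      e_antisocial = cfg$esteem$e_antisocial,
      e_self = cfg$esteem$e_self,
      beta_r = cfg$esteem$beta_r
    ),
    precision_prior = cfg$precision_prior,
    game = list(
      n_rounds = cfg$n_rounds, seed = cfg$seed,
      other_true_esteem = cfg$other_true_esteem
    ),
    engine = list(
      tol = cfg$tol, max_iter = cfg$max_iter,
      carry_precision = cfg$carry_precision
    )
  )
  if (!is.null(cfg$payoffs$fractions)) {
    out$payoffs$fractions <- lapply(cfg$payoffs$fractions, as.list)
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

# ---- trace serialization ----------------------------------------------------

trace_columns <- c("round", "action_self", "action_other", "observation",
                   "p_prosocial", "p_antisocial", "p_cooperate", "gamma_hat",
                   "free_energy", "n_iter")

fmt12 <- function(x) sprintf("%.12g", x)

#' Write a game trace to disk
#'
#' CSV: one row per round with a stable column order (`round, action_self,
#' action_other, observation, p_prosocial, p_antisocial, p_cooperate,
#' gamma_hat, free_energy, n_iter`), floats at 12 significant digits.
#' JSON: configuration, seed, per-round records and the package version.
#' [read_trace()] inverts either format, and a write-read-write cycle is
#' byte-identical.
#'
#' @param trace A [run_game()] trace.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- summarize_trace(trace)$rounds
  if (format == "csv") {
    write_rounds_csv(df, path)
  } else {
    payload <- list(
      version = trace$version,
      seed = trace$seed,
      config = config_to_list_for_json(trace$config),
      records = lapply(seq_len(nrow(df)), function(i) {
        r <- as.list(df[i, , drop = FALSE])
        r[vapply(r, is.double, logical(1))] <-
          lapply(r[vapply(r, is.double, logical(1))], function(x) as.numeric(fmt12(x)))
        r
      })
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

# canonical CSV writer for a rounds table (12 significant digits on floats)
write_rounds_csv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt12)
  lines <- c(paste(trace_columns, collapse = ","),
             do.call(paste, c(unname(df[trace_columns]), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

config_to_list_for_json <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  yaml::read_yaml(tmp)
}

#' Read a game trace written by [write_trace()]
#'
#' @param path Path to a `.csv` or `.json` trace file.
#' @return A list with `rounds` (data frame in the canonical column order)
#'   and, for JSON input, `config` (a [trust_config()]), `seed` and
#'   `version`.
#' @export
read_trace <- function(path) {
  if (grepl("\\.json$", path)) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    rounds <- as.data.frame(payload$records)[, trace_columns]
    cfg <- config_from_list(payload$config)
    list(rounds = rounds, config = cfg, seed = payload$seed,
         version = payload$version)
  } else {
    rounds <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!identical(names(rounds), trace_columns)) {
      stop("read_trace: unexpected trace columns in ", path)
    }
    list(rounds = rounds)
  }
}

# ---- random fixtures --------------------------------------------------------

#' Generate a random generative model for testing
#'
#' Dirichlet-sampled column-stochastic likelihood and transition tables, a
#' strictly positive goal prior and initial belief, and the full policy set
#' over the requested horizon. Seeded and reproducible; the result always
#' passes [validate_model()].
#'
#' @param n_states,n_observations,n_controls Dimensions (all >= 1).
#' @param horizon Policy length (>= 1).
#' @param seed RNG seed.
#' @param concentration Dirichlet concentration of the sampled columns
#'   (smaller = sparser-looking tables).
#' @param precision Gamma precision prior (defaults shape 8, scale 1).
#' @return A validated [generative_model()].
#' @export
generate_fixture <- function(n_states = 5, n_observations = 4, n_controls = 2,
                             horizon = 1, seed = 1, concentration = 1,
                             precision = list(shape = 8, scale = 1)) {
  stopifnot(n_states >= 1, n_observations >= 1, n_controls >= 1, horizon >= 1)
  set.seed(seed)
  rdirichlet_col <- function(n) {
    x <- stats::rgamma(n, shape = concentration) + 1e-12
    x / sum(x)
  }
  space <- state_space(
    hidden = paste0("s", seq_len(n_states)),
    observable = paste0("o", seq_len(n_observations)),
    obs_of_hidden = rep(seq_len(n_observations), length.out = n_states)
  )
  A <- vapply(seq_len(n_states), function(j) rdirichlet_col(n_observations),
              numeric(n_observations))
  A <- matrix(A, n_observations, n_states)
  B <- array(0, dim = c(n_states, n_states, n_controls))
  for (u in seq_len(n_controls)) {
    for (j in seq_len(n_states)) B[, j, u] <- rdirichlet_col(n_states)
  }
  goal <- rdirichlet_col(n_states)
  d <- rdirichlet_col(n_states)
  policies <- as.matrix(expand.grid(rep(list(seq_len(n_controls)), horizon)))
  dimnames(policies) <- NULL
  generative_model(
    space = space, A = A, B = B,
    goal = list(p_final = goal, beta = 1, returns = log(goal)),
    precision = precision, horizon = horizon,
    initial_belief = d, policies = policies,
    control_labels = paste0("u", seq_len(n_controls))
  )
}

# ---- command line -----------------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `run` (play a configured game and write trace files),
#' `round` (single-round demonstration printing belief tables), `calibrate`
#' (reward-sensitivity calibration report), `validate` (check a config
#' file), `fixtures` (emit a random test model as JSON). Flags `--config`,
#' `--seed`, `--rounds`, `--out`, `--format`, `--observe`, `--log-level`
#' override the configuration.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process's trailing arguments).
#' @return Integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    cli_dispatch(args)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_usage <- function() {
  paste(
    "usage: trustgame <run|round|calibrate|validate|fixtures> [options]",
    "  --config <path>   YAML configuration (defaults used when omitted)",
    "  --seed <int>      root RNG seed",
    "  --rounds <int>    number of rounds (run)",
    "  --out <path>      output path (run, fixtures)",
    "  --format <fmt>    csv or json (run)",
    "  --observe <obs>   outcome observation for `round` (cc, cd, dc, dd)",
    "  --log-level <lvl> quiet or info",
    sep = "\n"
  )
}

cli_parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, "\n", cli_usage())
    key <- sub("^--", "", a)
    if (!key %in% c("config", "seed", "rounds", "out", "format", "observe",
                    "log-level")) {
      stop("unknown flag: ", a, "\n", cli_usage())
    }
    if (i == length(args)) stop("flag ", a, " needs a value")
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

cli_config <- function(flags) {
  cfg <- if (!is.null(flags$config)) load_config(flags$config) else trust_config()
  if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
  if (!is.null(flags$rounds)) cfg$n_rounds <- as.integer(flags$rounds)
  if (cfg$n_rounds < 1) stop("config: `n_rounds` must be a count >= 1")
  cfg
}

cli_dispatch <- function(args) {
  if (length(args) == 0) stop("no subcommand\n", cli_usage())
  cmd <- args[1]
  flags <- cli_parse_flags(args[-1])
  quiet <- identical(flags[["log-level"]], "quiet")
  say <- function(...) if (!quiet) cat(..., "\n", sep = "")
  switch(cmd,
    run = {
      cfg <- cli_config(flags)
      trace <- run_game(cfg)
      out <- flags$out %||% "trace"
      fmt <- flags$format %||% "csv"
      path <- if (grepl("\\.(csv|json)$", out)) out else paste0(out, ".", fmt)
      write_trace(trace, path, format = fmt)
      s <- summarize_trace(trace)
      say(sprintf("wrote %d-round trace to %s", cfg$n_rounds, path))
      say(sprintf("cooperation rate %.3f; final P(antisocial) %.3f",
                  s$aggregates$cooperation_rate,
                  s$rounds$p_antisocial[nrow(s$rounds)]))
    },
    round = {
      cfg <- cli_config(flags)
      obs <- flags$observe %||% "dd"
      if (!obs %in% c("cc", "cd", "dc", "dd")) {
        stop("--observe must be one of cc, cd, dc, dd")
      }
      model <- build_self_model(cfg)
      pre <- infer(model, "start", tol = cfg$tol, max_iter = cfg$max_iter)
      action_self <- ACTIONS[1 + (substr(obs, 1, 1) == "d")]
      post <- infer(model, c("start", obs), actions = action_self,
                    tol = cfg$tol, max_iter = cfg$max_iter)
      s_final <- post$s_hat[[2]]
      traits <- trait_of_labels(model$space$hidden)
      cat("policy belief before the outcome:\n")
      print(round(stats::setNames(pre$u_hat, ACTIONS), 4))
      cat(sprintf("observed outcome: %s\n", obs))
      cat("posterior over hidden states:\n")
      print(round(stats::setNames(s_final, model$space$hidden), 4))
      cat(sprintf("trait posterior: P(prosocial) = %.4f, P(antisocial) = %.4f\n",
                  sum(s_final[traits == "p"]), sum(s_final[traits == "n"])))
      cat(sprintf("expected precision gamma_hat = %.4f\n", post$gamma_hat))
    },
    calibrate = {
      cfg <- cli_config(flags)
      b <- calibrate_beta_r(cfg$payoffs, cfg$esteem)
      cat(sprintf("calibrated beta_r = %.6g (largest value keeping every\n", b))
      cat("partner-response probability at or below 0.80)\n")
      for (us in ACTIONS) for (tr in TRAITS) {
        es <- cfg$esteem
        es$beta_r <- b
        r <- opponent_response(us, es, cfg$payoffs, tr)
        cat(sprintf("  self %-9s trait %s -> P(cooperate) = %.4f, P(defect) = %.4f\n",
                    us, tr, r[["cooperate"]], r[["defect"]]))
      }
    },
    validate = {
      cfg <- cli_config(flags)
      report <- validate_model(build_self_model(cfg))
      if (length(report)) stop(paste(report, collapse = "; "))
      say("configuration and constructed model are valid")
    },
    fixtures = {
      seed <- as.integer(flags$seed %||% "1")
      m <- generate_fixture(seed = seed)
      out <- flags$out %||% "fixture.json"
      jsonlite::write_json(
        list(hidden = m$space$hidden, observable = m$space$observable,
             A = m$A, B = m$B, goal = m$goal$p_final,
             initial_belief = m$initial_belief),
        out, digits = NA, pretty = TRUE)
      say("wrote fixture model to ", out)
    },
    stop("unknown subcommand: ", cmd, "\n", cli_usage())
  )
  invisible(NULL)
}
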