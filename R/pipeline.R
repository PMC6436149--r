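# End-to-end pipeline: synthetic campaign (or CSV inputs) -> per-sample
# fits -> per-group trait table with gate-tested comparisons.

#' Format a trait-table cell as "mean+/-SE" with significance flag
#' @param mean,se Numeric summary values (`se` may be `NA`).
#' @param significant Logical; `TRUE` appends the asterisk flag.
#' @param digits Significant digits (default 4).
#' @return Character scalar.
#' @export
format_trait_cell <- function(mean, se, significant = FALSE, digits = 4) {
  cell <- if (is.na(se)) signif(mean, digits) else
    paste0(signif(mean, digits), "±", signif(se, digits))
  if (isTRUE(significant)) paste0(cell, "*") else as.character(cell)
}

group_seed <- function(base, i, j) {
  # deterministic small sub-seed, kept well inside 32-bit range
  (base * 1000L + i * 100L + j) %% 2147483647L
}

simulate_group <- function(spec, base_seed, gi) {
  out <- list()
  if (!is.null(spec$vc)) {
    v <- spec$vc
    n <- if (is.null(v$n_shoots)) 5L else v$n_shoots
    noise <- if (is.null(v$noise_sd)) 5 else v$noise_sd
    fits <- lapply(seq_len(n), function(j) {
      d <- gen_vulnerability(v$a, v$p50, noise_sd = noise,
                             seed = group_seed(base_seed, gi, j))
      fit_sigmoid(d$pressure_mpa, d$percent)
    })
    out$vc <- data.frame(
      sample = seq_len(n),
      a = vapply(fits, `[[`, numeric(1L), "a"),
      p50 = vapply(fits, `[[`, numeric(1L), "p50"),
      p12 = vapply(fits, function(f) thresholds_of(f)$p12, numeric(1L)),
      p88 = vapply(fits, function(f) thresholds_of(f)$p88, numeric(1L))
    )
  }
  if (!is.null(spec$pv)) {
    p <- spec$pv
    n <- if (is.null(p$n_leaves)) 10L else p$n_leaves
    noise <- if (is.null(p$noise_sd_invpsi)) 0.01 else p$noise_sd_invpsi
    rows <- lapply(seq_len(n), function(j) {
      d <- gen_pv_leaf(p$psi_osat, p$w_tlp, noise_sd_invpsi = noise,
                       seed = group_seed(base_seed, gi + 50L, j))
      f <- tryCatch(fit_pv(d$wsd, inv_psi = d$inv_psi),
                    error = function(e) NULL)
      if (is.null(f)) return(NULL)
      data.frame(sample = j, psi_osat = f$psi_osat, psi_tlp = f$psi_tlp,
                 a_ela = f$a_ela)
    })
    out$pv <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  }
  if (!is.null(spec$conduits)) {
    cc <- spec$conduits
    n <- if (is.null(cc$n_sections)) 8L else cc$n_sections
    rows <- lapply(seq_len(n), function(j) {
      d <- gen_conduits(cc$median_um, cc$sigma_log,
                        n = if (is.null(cc$n)) 200L else cc$n,
                        seed = group_seed(base_seed, gi + 100L, j))
      data.frame(sample = j, d_mean = mean(d), d_h = hydraulic_diameter(d),
                 d_max = max(d))
    })
    out$conduits <- do.call(rbind, rows)
  }
  out
}

trait_params <- list(
  vc = c("a", "p50", "p12", "p88"),
  pv = c("psi_osat", "psi_tlp", "a_ela"),
  conduits = c("d_mean", "d_h", "d_max")
)
trait_organ <- c(vc = "branch", pv = "leaf", conduits = "branch")

#' Run the full analysis pipeline
#'
#' Generates (or reads) per-sample measurement series, fits every stage,
#' and assembles a trait table (rows = organ x parameter, columns = one
#' formatted "mean+/-SE" cell per group, asterisks from the gated tests).
#' Deterministic for a given config and seed.
#'
#' Config is a list (or path to a JSON file) with either
#' \describe{
#'   \item{`simulate`}{`groups`: list of group specs (`name`, optional
#'     `vc` = list(a, p50, n_shoots, noise_sd), `pv` = list(psi_osat,
#'     w_tlp, n_leaves, noise_sd_invpsi), `conduits` = list(median_um,
#'     sigma_log, n, n_sections)); optional `comparisons`: list of
#'     2-element group-name vectors tested pairwise.}
#'   \item{`input_dir`}{directory of `vc_*.csv` (pressure_mpa, percent)
#'     and `pv_*.csv` files; each is fitted and reported per sample.}
#' }
#'
#' @param config List or path to JSON config.
#' @param out_dir Optional output directory; when given, writes
#'   `traits.csv`, `samples.csv` and `gates.json`.
#' @param seed Base seed for all simulation (default 1).
#' @return List with `traits` (data.frame), `samples` (per-sample fits),
#'   `gates` (list of gate reports), `log` (design decisions exercised).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = 1L) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  if (!is.null(config$seed)) seed <- config$seed
  log <- c("unit convention: conductance kg s^-1 MPa^-1, water density 1 g cm^-3",
           "gate rule: Levene p < alpha selects Welch, else pooled Student")

  if (!is.null(config$input_dir)) {
    return(run_pipeline_files(config$input_dir, out_dir, log))
  }
  if (is.null(config$simulate)) {
    stop("config must contain `simulate` or `input_dir`", call. = FALSE)
  }
  groups <- config$simulate$groups
  if (!length(groups)) stop("no groups configured", call. = FALSE)
  names(groups) <- vapply(groups, `[[`, character(1L), "name")

  per_group <- lapply(seq_along(groups),
                      function(i) simulate_group(groups[[i]], seed, i))
  names(per_group) <- names(groups)

  # per-sample long table
  samples <- do.call(rbind, unlist(lapply(names(per_group), function(g) {
    lapply(names(per_group[[g]]), function(block) {
      df <- per_group[[g]][[block]]
      long <- utils::stack(df, select = setdiff(names(df), "sample"))
      data.frame(group = g, block = block,
                 sample = rep(df$sample, ncol(df) - 1L),
                 parameter = as.character(long$ind), value = long$values)
    })
  }), recursive = FALSE))

  # gated comparisons
  comparisons <- config$simulate$comparisons
  gates <- list()
  sig <- list()  # sig[[group2]][[param]] = TRUE
  if (length(comparisons)) {
    for (cmp in comparisons) {
      g1 <- cmp[[1L]]; g2 <- cmp[[2L]]
      if (!all(c(g1, g2) %in% names(per_group))) {
        stop("comparison names unknown group: ", paste(cmp, collapse = " vs "),
             call. = FALSE)
      }
      for (block in intersect(names(per_group[[g1]]), names(per_group[[g2]]))) {
        for (p in trait_params[[block]]) {
          a <- per_group[[g1]][[block]][[p]]
          b <- per_group[[g2]][[block]][[p]]
          gr <- tryCatch(gated_two_sample_test(a, b),
                         error = function(e) NULL, warning = function(w) {
                           suppressWarnings(gated_two_sample_test(a, b))
                         })
          if (is.null(gr)) next
          gates[[paste(g1, g2, p, sep = "|")]] <- list(
            groups = c(g1, g2), parameter = p,
            normality_p = gr$normality_p, variance_p = gr$variance_p,
            chosen_test = gr$chosen_test, test_p = gr$test_p,
            significant = gr$significant)
          if (isTRUE(gr$significant)) sig[[g2]] <- c(sig[[g2]], p)
        }
      }
    }
  }

  # trait table: organ x parameter rows, one formatted column per group
  rows <- list()
  for (block in names(trait_params)) {
    for (p in trait_params[[block]]) {
      present <- vapply(per_group, function(gp) !is.null(gp[[block]]),
                        logical(1L))
      if (!any(present)) next
      row <- list(organ = trait_organ[[block]], parameter = p)
      for (g in names(per_group)) {
        cell <- NA_character_
        if (!is.null(per_group[[g]][[block]])) {
          v <- per_group[[g]][[block]][[p]]
          cell <- format_trait_cell(mean(v), se_of(v), p %in% sig[[g]])
        }
        row[[g]] <- cell
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, check.names = FALSE)
    }
  }
  traits <- do.call(rbind, rows)

  res <- list(traits = traits, samples = samples, gates = gates, log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

run_pipeline_files <- function(input_dir, out_dir, log) {
  if (!dir.exists(input_dir)) {
    stop("input directory not found: ", input_dir, call. = FALSE)
  }
  vc_files <- list.files(input_dir, "^vc_.*\\.csv$", full.names = TRUE)
  pv_files <- list.files(input_dir, "^pv_.*\\.csv$", full.names = TRUE)
  if (!length(vc_files) && !length(pv_files)) {
    stop("validation error: no vc_*.csv or pv_*.csv inputs in ", input_dir,
         call. = FALSE)
  }
  rows <- list()
  for (f in vc_files) {
    d <- read_response_csv(f)
    fit <- fit_sigmoid(d$pressure_mpa, d$percent)
    th <- thresholds_of(fit)
    rows[[length(rows) + 1L]] <- data.frame(
      file = basename(f), kind = "vc", a = fit$a, p50 = fit$p50,
      p12 = th$p12, p88 = th$p88, psi_osat = NA, psi_tlp = NA, a_ela = NA,
      sse = fit$residual_sse, n = fit$n_points)
  }
  for (f in pv_files) {
    d <- read_pv_csv(f)
    fit <- fit_pv(d$wsd, d$psi_mpa)
    rows[[length(rows) + 1L]] <- data.frame(
      file = basename(f), kind = "pv", a = NA, p50 = NA, p12 = NA, p88 = NA,
      psi_osat = fit$psi_osat, psi_tlp = fit$psi_tlp, a_ela = fit$a_ela,
      sse = fit$sse, n = fit$n_points)
  }
  res <- list(traits = do.call(rbind, rows), samples = NULL, gates = list(),
              log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_traits_csv(res$traits, file.path(out_dir, "traits.csv"))
  if (!is.null(res$samples)) {
    write_traits_csv(res$samples, file.path(out_dir, "samples.csv"))
  }
  jsonlite::write_json(list(gates = res$gates, log = res$log),
                       file.path(out_dir, "gates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
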