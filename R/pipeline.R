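# Per-species orchestration and the comparative stability report: assembles
# classification, geometry comparison, activation free energy and Eyring
# kinetics into one record per species, then groups records by (class,
# anionic state) with As/P and monoester/diester rate ratios.

#' Analyse one ester species
#'
#' Fills every derivable field of a species record from whatever inputs are
#' supplied: a reactant geometry (classification), a paired TS geometry
#' with parameter specs (geometry table), and exactly one kinetic route --
#' an activation free energy, an observed rate constant, or electronic
#' energies plus frequencies for reactant and TS. Missing optional inputs
#' yield `NULL` fields, never silent defaults. Supplying both `dg_act` and
#' `rate_constant` is allowed only when they agree through the Eyring
#' round-trip within `consistency_tol`.
#'
#' @param label Species label.
#' @param geom Optional reactant `geometry`.
#' @param ts_geom Optional transition-state `geometry`.
#' @param param_specs Optional list of [param_spec()] for the geometry
#'   table (requires both geometries).
#' @param dg_act Optional activation free energy, kcal/mol.
#' @param rate_constant Optional first-order rate constant, s^-1.
#' @param energies Optional list
#'   `list(reactant = list(electronic_energy, frequencies, geometry),
#'   ts = list(...))` (kcal/mol, [frequency_set()]s); geometries default to
#'   `geom` / `ts_geom`.
#' @param asm Optional [fragment_energies()] for an activation strain
#'   decomposition.
#' @param temperature Temperature in K (default 298).
#' @param c_std Standard-state factor (default 1).
#' @param consistency_tol Tolerance (kcal/mol) between a supplied `dg_act`
#'   and the one implied by a supplied rate (default 0.1).
#' @return Object of class `"species_record"`.
#' @export
run_species <- function(label, geom = NULL, ts_geom = NULL,
                        param_specs = NULL, dg_act = NULL,
                        rate_constant = NULL, energies = NULL, asm = NULL,
                        temperature = 298, c_std = 1,
                        consistency_tol = 0.1) {
  warnings_seen <- character(0)
  note <- function(w) warnings_seen <<- c(warnings_seen, w)

  classification <- NULL
  if (!is.null(geom)) {
    classification <- withCallingHandlers(
      classify_ester(geom),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    if (classification$ambiguous) {
      note("reaction center ambiguous (tie broken by lowest serial)")
    }
  }

  geometry_table <- NULL
  if (!is.null(param_specs)) {
    if (is.null(geom) || is.null(ts_geom)) {
      stop("param_specs require both reactant and TS geometries")
    }
    geometry_table <- parameter_table(geom, ts_geom, param_specs)
  }

  asm_result <- NULL
  if (!is.null(asm)) asm_result <- asm_decompose(asm)

  if (!is.null(energies)) {
    if (!is.null(dg_act)) {
      stop("supply either energies+frequencies or dg_act, not both")
    }
    get_g <- function(side, default_geom) {
      e <- energies[[side]]
      gg <- if (!is.null(e$geometry)) e$geometry else default_geom
      if (is.null(gg)) {
        stop("energies$", side, " needs a geometry for the RRHO terms")
      }
      th <- rrho_corrections(gg, e$frequencies, temperature = temperature)
      gibbs_free_energy(e$electronic_energy, th)
    }
    dg_act <- withCallingHandlers(
      activation_free_energy(get_g("reactant", geom), get_g("ts", ts_geom)),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
  }

  rate <- NULL
  if (!is.null(dg_act) && !is.null(rate_constant)) {
    implied <- invert_eyring(rate_constant, temperature, c_std)
    if (abs(implied - dg_act) > consistency_tol) {
      stop("consistency error: supplied rate constant implies dG_act = ",
           signif(implied, 6), " kcal/mol but dG_act = ",
           signif(dg_act, 6), " was given (tolerance ", consistency_tol,
           ")")
    }
  }
  if (!is.null(dg_act)) {
    rate <- withCallingHandlers(
      eyring_rate(dg_act, temperature, c_std),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
  } else if (!is.null(rate_constant)) {
    dg_act <- invert_eyring(rate_constant, temperature, c_std)
    rate <- eyring_rate(dg_act, temperature, c_std)
  }

  structure(list(label = as.character(label),
                 classification = classification,
                 geometry_table = geometry_table,
                 asm = asm_result,
                 dg_act = dg_act, rate = rate,
                 temperature = temperature,
                 warnings = warnings_seen),
            class = "species_record")
}

#' @export
print.species_record <- function(x, ...) {
  cat("<species_record>", x$label, "\n")
  if (!is.null(x$classification)) {
    cat(sprintf("  class %s %s, central %s, %s-anionic\n",
                x$classification$ester_class, x$classification$ester_type,
                x$classification$central_atom,
                x$classification$anionic_state))
  }
  if (!is.null(x$rate)) {
    cat(sprintf("  dG_act %.2f kcal/mol, k %s s^-1 at %g K\n",
                x$dg_act,
                format(x$rate$rate_constant, digits = 3, scientific = TRUE),
                x$temperature))
  }
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

.record_field <- function(r, what) {
  cl <- r$classification
  switch(what,
    class = if (is.null(cl)) NA_character_ else cl$ester_class,
    type = if (is.null(cl)) NA_character_ else cl$ester_type,
    central = if (is.null(cl)) NA_character_ else cl$central_atom,
    anion = if (is.null(cl)) NA_character_ else cl$anionic_state)
}

#' Build the comparative stability report
#'
#' Groups species records by (ester class, anionic state), ranks them by
#' rate constant, and computes two ratio families: the As/P rate ratio
#' within each (class, anion) cell where both central atoms are present,
#' and the monoester-versus-diester cross ratio per central atom (the rate
#' of the dianionic class 1B monoester over the rate of the monoanionic
#' class 2 diester -- how many times more stable the diester backbone is
#' than the sugar monoester feeding its synthesis).
#'
#' @param records A list of [run_species()] records (a single record is
#'   accepted).
#' @return Object of class `"stability_report"`: `table` (one row per
#'   species, ranked), `as_p_ratios`, `cross_ratios`, `footnotes`
#'   (collected per-species warnings).
#' @export
build_report <- function(records) {
  if (inherits(records, "species_record")) records <- list(records)
  if (length(records) == 0L) stop("at least one species record required")
  stopifnot(all(vapply(records, inherits, logical(1), "species_record")))
  tab <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      label = r$label,
      class = .record_field(r, "class"),
      ester_type = .record_field(r, "type"),
      central = .record_field(r, "central"),
      anion = .record_field(r, "anion"),
      dg_act = if (is.null(r$dg_act)) NA_real_ else r$dg_act,
      rate_constant = if (is.null(r$rate)) NA_real_ else
        r$rate$rate_constant,
      log_rate = if (is.null(r$rate)) NA_real_ else r$rate$log_rate,
      half_life = if (is.null(r$rate)) NA_real_ else r$rate$half_life,
      temperature = r$temperature,
      stringsAsFactors = FALSE)
  }))
  # canonical order: class, anion (mono before di), As before P, label
  ord <- order(tab$class,
               match(tab$anion, c("mono", "di")),
               match(tab$central, c("As", "P")),
               tab$label)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab$rank_by_rate <- NA_integer_
  has_rate <- which(!is.na(tab$log_rate))
  tab$rank_by_rate[has_rate] <- rank(-tab$log_rate[has_rate],
                                     ties.method = "min")

  ratio_rows <- NULL
  cells <- unique(tab[!is.na(tab$class) & !is.na(tab$anion),
                      c("class", "anion")])
  if (nrow(cells)) {
    for (k in seq_len(nrow(cells))) {
      sel <- tab$class == cells$class[k] & tab$anion == cells$anion[k] &
        !is.na(tab$class) & !is.na(tab$anion)
      a <- tab[sel & tab$central == "As" & !is.na(tab$log_rate), ]
      p <- tab[sel & tab$central == "P" & !is.na(tab$log_rate), ]
      if (nrow(a) == 1L && nrow(p) == 1L) {
        ratio_rows <- rbind(ratio_rows, data.frame(
          class = cells$class[k], anion = cells$anion[k],
          ratio_As_over_P = exp(a$log_rate - p$log_rate),
          stringsAsFactors = FALSE))
      }
    }
  }
  cross_rows <- NULL
  for (ce in c("As", "P")) {
    mono_di <- tab[!is.na(tab$class) & tab$class == "1B" &
                     tab$anion == "di" & tab$central == ce &
                     !is.na(tab$log_rate), ]
    diester <- tab[!is.na(tab$class) & tab$class == "2" &
                     tab$anion == "mono" & tab$central == ce &
                     !is.na(tab$log_rate), ]
    if (nrow(mono_di) == 1L && nrow(diester) == 1L) {
      cross_rows <- rbind(cross_rows, data.frame(
        central = ce,
        ratio_monoester_di_over_diester_mono =
          exp(mono_di$log_rate - diester$log_rate),
        stringsAsFactors = FALSE))
    }
  }
  foot <- unlist(lapply(records, function(r) {
    if (length(r$warnings)) paste0(r$label, ": ", r$warnings)
  }))
  structure(list(table = tab, as_p_ratios = ratio_rows,
                 cross_ratios = cross_rows,
                 footnotes = sort(unique(foot))),
            class = "stability_report")
}

.sci <- function(x, digits = 3) {
  ifelse(is.na(x), "-", formatC(x, format = "e", digits = digits - 1))
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Comparative kinetic stability (first-order hydrolysis)\n")
  t <- x$table
  disp <- data.frame(label = t$label, class = t$class, anion = t$anion,
                     `k (s^-1)` = .sci(t$rate_constant),
                     `dG_act` = ifelse(is.na(t$dg_act), "-",
                                       sprintf("%.2f", t$dg_act)),
                     `t1/2 (s)` = .sci(t$half_life),
                     rank = t$rank_by_rate,
                     check.names = FALSE, stringsAsFactors = FALSE)
  print(disp, row.names = FALSE)
  if (!is.null(x$as_p_ratios)) {
    cat("\nAs/P rate ratios by (class, anion):\n")
    r <- x$as_p_ratios
    for (k in seq_len(nrow(r))) {
      cat(sprintf("  class %s %s-anionic: %s\n", r$class[k], r$anion[k],
                  .sci(r$ratio_As_over_P[k])))
    }
  }
  if (!is.null(x$cross_ratios)) {
    cat("\nmonoester(di) / diester(mono) rate ratios:\n")
    r <- x$cross_ratios
    for (k in seq_len(nrow(r))) {
      cat(sprintf("  %s: %s\n", r$central[k],
                  .sci(r$ratio_monoester_di_over_diester_mono[k])))
    }
  }
  if (length(x$footnotes)) {
    cat("\nnotes:\n")
    for (f in x$footnotes) cat("  -", f, "\n")
  }
  invisible(x)
}

#' Export a stability report as TSV or JSON
#'
#' Deterministic rendering: identical records (in any order) give
#' byte-identical output. Every number is taken from a record field; the
#' renderer computes nothing.
#'
#' @param report A `stability_report`.
#' @param file Output path; if `NULL` the text is returned invisibly.
#' @param format `"tsv"` or `"json"`.
#' @return Serialized text, invisibly.
#' @export
write_stability_report <- function(report, file = NULL,
                                   format = c("tsv", "json")) {
  stopifnot(inherits(report, "stability_report"))
  format <- match.arg(format)
  if (format == "tsv") {
    t <- report$table
    hdr <- paste(names(t), collapse = "\t")
    fmt_num <- function(v) ifelse(is.na(v), "NA",
                                  formatC(v, format = "e", digits = 12))
    body <- paste(t$label, t$class, t$ester_type, t$central, t$anion,
                  fmt_num(t$dg_act), fmt_num(t$rate_constant),
                  fmt_num(t$log_rate), fmt_num(t$half_life),
                  t$temperature, t$rank_by_rate, sep = "\t")
    txt <- paste(c(hdr, body), collapse = "\n")
  } else {
    txt <- as.character(jsonlite::toJSON(
      list(table = report$table, as_p_ratios = report$as_p_ratios,
           cross_ratios = report$cross_ratios,
           footnotes = report$footnotes),
      digits = NA, dataframe = "rows", null = "null"))
  }
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
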