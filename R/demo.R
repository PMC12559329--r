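#' End-to-end demonstration scenarios
#'
#' Two bundled scenarios tie the modules together on the standard
#' (CAG)4-loop substrate:
#' * the expansion scenario plants loop-recognition incisions on the
#'   strand opposite the loop (decaying 5' of the loop), maps them, and
#'   decomposes an opposite-strand trace mixture carrying the (CTG)4
#'   insertion;
#' * the contraction scenario plants the FAN1-like incision one
#'   nucleotide 3' of the loop on the looped strand, maps it, and
#'   decomposes a looped-strand trace mixture in which most molecules
#'   have lost the (CAG)4 loop.
#'
#' Every artifact is written under one report directory; all
#' randomness flows from the single `seed` entry of the config, so an
#' identical config reproduces byte-identical tables.
#'
#' @name demo
NULL

#' Default run configuration
#'
#' All tunable parameters of the pipeline in one structured list; any
#' subset can be overridden. `validate_config()` checks types and
#' ranges and is applied to every demo run.
#'
#' @param overrides named list of values replacing the defaults.
#' @return a `run_config` list.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    plasmid_length = 3200L,
    gc_fraction = 0.5,
    loop_sequence = "CAGCAGCAGCAG",
    carrier_strand = "top",
    insertion_point = 1600L,
    n_reads = 20000L,
    read_length = 75L,
    error_rate = 0,
    seed_k = 20L,
    max_mismatches = 2L,
    copies = "middle",
    rescue_reference = "looped",
    insertion_fraction = 0.155,   # expansion-product share in the trace mix
    contraction_fraction = 0.75,  # loop-loss share in the trace mix
    trace_noise_sd = 0.01,
    trace_decay = 0.001,
    shift_range = -15:15,
    alpha = 0.001)
  cfg[names(overrides)] <- overrides
  validate_config(cfg)
}

#' @rdname default_config
#' @param cfg a config list.
#' @export
validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) abort_invalid(paste0("config: ", msg))
  chk(is.numeric(cfg$seed), "seed must be numeric")
  chk(cfg$plasmid_length >= 100, "plasmid_length must be >= 100")
  chk(is_dna_string(toupper(cfg$loop_sequence)), "loop_sequence must be A/C/G/T")
  chk(cfg$carrier_strand %in% c("top", "bottom"), "carrier_strand invalid")
  chk(cfg$n_reads >= 0, "n_reads must be >= 0")
  chk(cfg$error_rate >= 0 && cfg$error_rate < 1, "error_rate must be in [0,1)")
  chk(cfg$insertion_fraction >= 0 && cfg$insertion_fraction <= 1,
      "insertion_fraction must be in [0,1]")
  chk(cfg$contraction_fraction >= 0 && cfg$contraction_fraction <= 1,
      "contraction_fraction must be in [0,1]")
  chk(cfg$copies %in% c("middle", "all"), "copies must be 'middle' or 'all'")
  chk(cfg$rescue_reference %in% c("looped", "loopless"),
      "rescue_reference invalid")
  structure(cfg, class = "run_config")
}

#' Build the scenario's standard substrate from a config
#' @param cfg a `run_config`.
#' @return a `heteroduplex`.
#' @export
config_substrate <- function(cfg) {
  seeds <- derive_seeds(cfg$seed, 4L)
  p <- generate_plasmid(cfg$plasmid_length, cfg$gc_fraction, seeds[1])
  make_heteroduplex(p, loop_spec(cfg$carrier_strand, cfg$insertion_point,
                                 toupper(cfg$loop_sequence)))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

demo_core <- function(cfg, out_dir, scenario) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(cfg$seed, 4L)
  log <- function(...) message(sprintf(...))

  sub <- run_stage("substrate", config_substrate(cfg))
  write_substrate(sub, file.path(out_dir, "substrate.json"))
  log("[%s] substrate: %d nt plasmid, %d-nt loop at %d (%s strand)",
      scenario, sub$plasmid$length_nt, sub$loop$loop_length,
      sub$loop$insertion_point, sub$loop$carrier_strand)

  preset <- if (scenario == "expansion") "mutl_opposite_5prime"
            else "fan1_loop3prime"
  profile <- run_stage("nick profile", preset_profile(preset, sub))
  reads <- run_stage("read simulation",
                     simulate_reads(profile, cfg$n_reads, cfg$read_length,
                                    cfg$error_rate, seed = seeds[2]))
  write_fastq(reads, file.path(out_dir, "reads.fastq"))
  write_truth(reads, file.path(out_dir, "truth.tsv"))

  cuts <- run_stage("nick mapping", map_nicks(
    sub, reads,
    params = list(seed_k = cfg$seed_k, max_mismatches = cfg$max_mismatches),
    copies = cfg$copies, rescue_reference = cfg$rescue_reference))
  files <- export_profile(cuts, file.path(out_dir, "cuts"))
  log("[%s] mapping: %d/%d reads placed (%d rescued, %d ambiguous)",
      scenario, cuts$totals$n_unique_primary + cuts$totals$n_rescued,
      cuts$totals$n_input, cuts$totals$n_rescued, cuts$totals$n_ambiguous)

  event <- if (scenario == "expansion") "expansion" else "contraction"
  ctx <- run_stage("trace context", sanger_context(sub, event))
  mix_frac <- if (scenario == "expansion") cfg$insertion_fraction
              else cfg$contraction_fraction
  mutant <- run_stage("trace simulation", simulate_trace(
    data.frame(sequence = c(ctx$control, ctx$product),
               fraction = c(1 - mix_frac, mix_frac)),
    decay_rate = cfg$trace_decay, noise_sd = cfg$trace_noise_sd,
    seed = seeds[3]))
  write_chromatogram(mutant, file.path(out_dir, "mutant_trace.tsv"))
  tpl <- run_stage("templates", build_templates(
    ctx$control, ctx$target_site, cfg$shift_range,
    expected_insert_bases = ctx$insert_unit, decay_rate = cfg$trace_decay))
  dec <- run_stage("decomposition", decompose(mutant, tpl, cfg$alpha))
  export_decomposition(dec, file.path(out_dir, "trace"), sub)
  summ <- summarize_indels(dec, sub)
  log("[%s] decomposition: dominant shift %+d nt, insertion %.1f%%, shortening %.1f%%",
      scenario, summ$dominant_shift,
      100 * summ$insertion_fraction, 100 * summ$shortening_fraction)

  # machine-readable run summary, with stage input/output checksums
  out_files <- list.files(out_dir, full.names = TRUE)
  out_files <- out_files[!grepl("run_summary\\.json$|\\.svg$|\\.png$",
                                out_files)]
  modal <- modal_cut(cuts)
  summary <- list(
    scenario = scenario,
    config = cfg[setdiff(names(cfg), "shift_range")],
    shift_range = range(cfg$shift_range),
    totals = cuts$totals,
    modal_cut = modal,
    decomposition = summ$table,
    checksums = as.list(tools::md5sum(sort(out_files))))
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(substrate = sub, profile = profile, reads = reads,
                 cuts = cuts, decomposition = dec, summary = summ,
                 files = out_dir))
}

#' Modal cut position per strand of a cut profile
#'
#' @param cuts a `cut_profile`.
#' @return list with, per strand role, the plasmid coordinate of the
#'   maximal cut count, its looped-strand coordinate, and its offset
#'   from the loop 3' boundary along the looped strand.
#' @export
modal_cut <- function(cuts) {
  sub <- cuts$substrate
  lab <- strand_labels(sub)
  counts_carrier <- if (lab$carrier == "top") cuts$counts_top
                    else cuts$counts_bottom
  counts_opp <- if (lab$carrier == "top") cuts$counts_bottom
                else cuts$counts_top
  res <- list()
  if (any(counts_carrier > 0)) {
    pmax_ <- which.max(counts_carrier) - 1L
    lm <- coord_map(sub, pmax_, "duplex", "looped_strand")
    res$looped_strand <- list(
      plasmid_position = pmax_,
      looped_position = as.integer(lm),
      offset_from_loop3 = as.integer(lm) - sub$loop3_boundary)
  }
  if (any(counts_opp > 0))
    res$opposite_strand <- list(
      plasmid_position = which.max(counts_opp) - 1L)
  res
}

#' Run the repeat-expansion demonstration
#'
#' Plants loop-recognition incisions opposite a (CAG)4 loop, maps them,
#' and decomposes an opposite-strand trace mixture carrying the (CTG)4
#' insertion at the configured insertion fraction.
#'
#' @param out_dir report directory (created if needed).
#' @param config named list of overrides for [default_config()].
#' @return invisibly, a list of in-memory stage results; all artifacts
#'   are written under `out_dir`.
#' @export
run_expansion_demo <- function(out_dir, config = list()) {
  demo_core(default_config(config), out_dir, "expansion")
}

#' Run the repeat-contraction demonstration
#'
#' Plants the FAN1-like incision one nucleotide 3' of the loop on the
#' looped strand, maps it, and decomposes a looped-strand trace mixture
#' in which the configured fraction of molecules lost the loop.
#'
#' @inheritParams run_expansion_demo
#' @export
run_contraction_demo <- function(out_dir, config = list()) {
  demo_core(default_config(config), out_dir, "contraction")
}
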