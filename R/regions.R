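# The nine structural region labels of the catalytic dimer, expressed as
# sets of alignment columns.

#' The fixed vocabulary of structural region labels
#' @export
REGION_LABELS <- c("FormI_LL_interface", "FormI_LS_interface",
                   "FormIII_LL_interface", "dimer_interface",
                   "barrel_strands", "near_barrel", "loop6",
                   "N_terminal", "C_terminal")

#' Region-annotation configuration
#'
#' @param cutoff Interface cutoff in Angstrom (strict `<`, default 5 to
#'   include nonpolar interactions).
#' @param formI Reference for the Form I interfaces: list with `model` (a
#'   `structure_model` or PDB path), `dimer_chains` (two chain ids of the
#'   catalytic dimer), `partner_ll_chains` (neighboring large subunits) and
#'   `partner_ls_chains` (small subunits).
#' @param formIII Reference for the Form III large-large interface: list
#'   with `model`, `dimer_chains`, `partner_chains`.
#' @param subdomain Reference carrying the subdomain definitions: list with
#'   `model`, and integer residue numbers (reference numbering, first dimer
#'   chain) `barrel_strands`, `loop6`, `n_terminal`, `c_terminal`.
#' @param near_barrel_excludes_core Whether `near_barrel` excludes the
#'   barrel strands themselves (default `TRUE`).
#' @return Object of class `region_config`.
#' @export
region_config <- function(cutoff = 5, formI = NULL, formIII = NULL,
                          subdomain = NULL,
                          near_barrel_excludes_core = TRUE) {
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop_pe("config_error", "cutoff must be > 0")
  structure(list(cutoff = cutoff, formI = formI, formIII = formIII,
                 subdomain = subdomain,
                 near_barrel_excludes_core = near_barrel_excludes_core),
            class = "region_config")
}

as_structure <- function(x) {
  if (inherits(x, "structure_model")) x else read_structure(x)
}

#' Construct a region map directly from column sets
#'
#' @param columns Named list label -> integer vector of alignment columns
#'   (1-based); names must come from [REGION_LABELS].
#' @param provenance Free-form list recorded with the map.
#' @return Object of class `region_map`.
#' @export
region_map <- function(columns, provenance = list()) {
  bad <- setdiff(names(columns), REGION_LABELS)
  if (length(bad))
    stop_pe("config_error", "unknown region labels: %s",
            paste(bad, collapse = " "))
  missing <- setdiff(REGION_LABELS, names(columns))
  columns[missing] <- list(integer(0))
  columns <- lapply(columns[REGION_LABELS],
                    function(x) sort(unique(as.integer(x))))
  structure(list(columns = columns, provenance = provenance),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map>\n")
  for (nm in names(x$columns))
    cat(sprintf("  %-22s %d columns\n", nm, length(x$columns[[nm]])))
  invisible(x)
}

#' Annotate the nine structural regions as alignment columns
#'
#' Runs the geometric rules against a query dimer: three cross-model
#' interfaces (Form I large-large, Form I large-small, Form III
#' large-large) by superimposing the query onto reference complexes and
#' measuring heavy-atom distances to the partner chains; the dimer
#' interface within the query itself; barrel strands, loop 6 and the two
#' termini transferred from a subdomain reference by nearest Calpha; and
#' the near-barrel shell around the barrel strands.  Residue numbers are
#' then mapped to alignment columns through the row of `reference_row` in
#' the alignment (the two dimer chains are assumed to share numbering).
#'
#' @param config A [region_config()].
#' @param query A `structure_model` (or PDB path) of the query dimer; its
#'   first chain's sequence must match the ungapped `reference_row`.
#' @param alignment A [protein_alignment()].
#' @param reference_row Taxon name of the alignment row corresponding to
#'   the query structure.
#' @return A [region_map()] with provenance (cutoff, references used).
#' @export
build_region_map <- function(config, query, alignment, reference_row) {
  stopifnot(inherits(config, "region_config"))
  query <- as_structure(query)
  if (!reference_row %in% rownames(alignment))
    stop_pe("input_error", "taxon '%s' not in alignment", reference_row)
  qchains <- unique(query$chain)
  chain1 <- qchains[1]
  seq1 <- query[query$atom == "CA" & query$chain == chain1, "resid"]
  seq1 <- names(AA3_CODES)[match(seq1, AA3_CODES)]
  mapping <- map_residues_to_alignment(seq1, alignment[reference_row, ])
  resno1 <- unique(query$resno[query$chain == chain1])

  keys_to_cols <- function(keys) {
    idx <- match(key_resno(keys), resno1)
    sort(unique(mapping$column[idx[!is.na(idx)]]))
  }
  run_stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop_pe("region_error", "[%s] %s", label, conditionMessage(e)))
  }

  cols <- list()
  cutoff <- config$cutoff
  if (!is.null(config$formI)) {
    refI <- as_structure(config$formI$model)
    cols$FormI_LL_interface <- run_stage("FormI_LL_interface",
      keys_to_cols(cross_model_interface(query, refI,
        config$formI$partner_ll_chains, cutoff = cutoff)))
    cols$FormI_LS_interface <- run_stage("FormI_LS_interface",
      keys_to_cols(cross_model_interface(query, refI,
        config$formI$partner_ls_chains, cutoff = cutoff)))
  }
  if (!is.null(config$formIII)) {
    refIII <- as_structure(config$formIII$model)
    cols$FormIII_LL_interface <- run_stage("FormIII_LL_interface",
      keys_to_cols(cross_model_interface(query, refIII,
        config$formIII$partner_chains, cutoff = cutoff)))
  }
  if (length(qchains) >= 2) {
    cols$dimer_interface <- run_stage("dimer_interface", keys_to_cols(c(
      interface_residues(query, qchains[1], qchains[2], cutoff),
      interface_residues(query, qchains[2], qchains[1], cutoff))))
  }
  if (!is.null(config$subdomain)) {
    sref <- as_structure(config$subdomain$model)
    sref_chain <- unique(sref$chain)[1]
    sub_keys <- function(resnos) {
      if (length(resnos) == 0) return(character(0))
      if (is.character(resnos)) resnos else res_key(sref_chain, resnos)
    }
    transfer <- function(label, resnos) {
      if (length(resnos) == 0) return(integer(0))
      run_stage(label, keys_to_cols(
        subdomain_by_nearest_ca(query, sref, sub_keys(resnos))))
    }
    cols$barrel_strands <- transfer("barrel_strands",
                                    config$subdomain$barrel_strands)
    cols$loop6 <- transfer("loop6", config$subdomain$loop6)
    cols$N_terminal <- transfer("N_terminal", config$subdomain$n_terminal)
    cols$C_terminal <- transfer("C_terminal", config$subdomain$c_terminal)
    if (length(cols$barrel_strands)) {
      barrel_resnos <- resno1[match(cols$barrel_strands, mapping$column)]
      barrel_keys <- c(res_key(qchains[1], barrel_resnos),
                       if (length(qchains) >= 2)
                         res_key(qchains[2], barrel_resnos))
      near <- run_stage("near_barrel",
                        near_set(query, barrel_keys, cutoff))
      near_cols <- keys_to_cols(near)
      if (config$near_barrel_excludes_core)
        near_cols <- setdiff(near_cols, cols$barrel_strands)
      cols$near_barrel <- near_cols
    }
  }
  region_map(cols, provenance = list(cutoff = cutoff,
                                     reference_row = reference_row,
                                     query_chains = qchains))
}

#' Write a region map as TSV (and optionally JSON)
#'
#' @param rmap A [region_map()].
#' @param path Output TSV path (columns: `column`, `regions`
#'   comma-separated); a provenance header line is included.  With a
#'   `.json` extension the map is written as JSON instead.
#' @export
write_region_map <- function(rmap, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(columns = rmap$columns,
                              provenance = rmap$provenance),
                         path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  all_cols <- sort(unique(unlist(rmap$columns)))
  lab <- vapply(all_cols, function(cc)
    paste(names(rmap$columns)[vapply(rmap$columns, function(v) cc %in% v,
                                     logical(1))], collapse = ","),
    character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# region_map cutoff=%s reference_row=%s",
                     rmap$provenance$cutoff %||% "NA",
                     rmap$provenance$reference_row %||% "NA"), con)
  writeLines("column\tregions", con)
  if (length(all_cols))
    writeLines(paste(all_cols, lab, sep = "\t"), con)
  invisible(path)
}

#' Read a region map written by [write_region_map()]
#' @param path TSV path.
#' @return A [region_map()].
#' @export
read_region_map <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  tab <- read.table(text = lines[!hdr], sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  cols <- setNames(lapply(REGION_LABELS, function(lb) {
    tab$column[vapply(strsplit(tab$regions, ","),
                      function(v) lb %in% v, logical(1))]
  }), REGION_LABELS)
  region_map(cols)
}
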