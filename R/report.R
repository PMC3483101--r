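# Report assembly and export: a deterministic bundle of summary and tables,
# written as versioned JSON, CSV tables, and a static colour-coded HTML page.

REPORT_SCHEMA_VERSION <- "1.0"

#' Assemble a report bundle from a validation result
#'
#' @param v a `"rog_validation"` from [validate_project()].
#' @return list of class `"rog_report"`: `summary`, `per_residue`,
#'   `restraints` (one table per list), `shifts`, `interactions`, `ranges`,
#'   `records`; all tables deterministically ordered (chain, seq,
#'   criterion).
#' @export
build_report <- function(v) {
  dr_tables <- lapply(v$distance_restraints, function(rl) rl$table)
  names(dr_tables) <- vapply(v$distance_restraints, function(rl) rl$name, "")
  dh_tables <- lapply(v$dihedral_restraints, function(rl) rl$table)
  names(dh_tables) <- vapply(v$dihedral_restraints, function(rl) rl$name, "")
  class_counts <- table(unlist(lapply(v$distance_restraints,
                                      function(rl) rl$classes)))
  n_dupl <- sum(vapply(v$distance_restraints, function(rl)
    attr(rl$duplicates, "n_duplicates") %||% 0L, 1L))
  summary <- list(
    name = v$name,
    molecule_rog = as.character(v$molecule_rog),
    pct_green = v$pct_green, pct_orange = v$pct_orange, pct_red = v$pct_red,
    n_models = v$molecule$M,
    n_residues = nrow(v$residues),
    n_range_residues = nrow(v$range$included),
    range = paste0(v$range$segments$chain, ":", v$range$segments$first, "-",
                   v$range$segments$last, collapse = ","),
    rmsd_to_mean = if (!is.null(v$superposition))
      v$superposition$rmsd_mean else NA,
    rmsd_sd = if (!is.null(v$superposition)) v$superposition$rmsd_sd else NA,
    closest_model = if (!is.null(v$superposition))
      v$superposition$closest_model else NA,
    n_distance_restraints = sum(vapply(v$distance_restraints, function(rl)
      length(rl$restraints), 1L)),
    n_dihedral_restraints = sum(vapply(v$dihedral_restraints, function(rl)
      length(rl$restraints), 1L)),
    restraint_classes = as.list(class_counts),
    n_duplicates = n_dupl,
    noe_completeness = if (!is.null(v$completeness))
      v$completeness$overall_completeness else NA)
  recs <- v$records
  recs <- recs[order(recs$entity_path, recs$criterion), , drop = FALSE]
  rownames(recs) <- NULL
  res <- v$residues[order(v$residues$chain, v$residues$seq), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(schema_version = REPORT_SCHEMA_VERSION, summary = summary,
                 per_residue = res, chains = v$chains,
                 restraints = c(dr_tables, dh_tables),
                 shifts = if (!is.null(v$shift_analysis))
                   v$shift_analysis$table else NULL,
                 interactions = list(salt_bridges = v$salt_bridges,
                                     disulfides = v$disulfides),
                 ranges = v$range$segments,
                 ss_consensus = v$ss_consensus,
                 records = recs),
            class = "rog_report")
}

.rog_color <- c(green = "#2e7d32", orange = "#ef6c00", red = "#c62828")

#' Export a report bundle
#'
#' `"json"` writes the whole bundle as one versioned JSON file; `"csv"`
#' writes one CSV per table; `"html"` writes a static, script-free page
#' with ROG colour-coding.
#'
#' @param report a `"rog_report"`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("json", "csv", "html")`.
#' @return invisibly, the paths written.
#' @export
export_report <- function(report, dir, formats = c("json", "csv", "html")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(unclass(report), p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("csv" %in% formats) {
    wr <- function(df, nm) {
      if (is.null(df) || !nrow(df)) return(invisible(NULL))
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(df, p, row.names = FALSE)
      paths <<- c(paths, p)
    }
    wr(report$per_residue, "per_residue")
    wr(report$records, "records")
    for (nm in names(report$restraints))
      wr(report$restraints[[nm]],
         paste0("restraints_", gsub("[^A-Za-z0-9._-]", "_", nm)))
    wr(report$shifts, "shifts")
    wr(report$interactions$salt_bridges, "salt_bridges")
    wr(report$interactions$disulfides, "disulfides")
    wr(report$ranges, "ranges")
  }
  if ("html" %in% formats) {
    p <- file.path(dir, "report.html")
    writeLines(.render_html(report), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.html_table <- function(df, rog_col = "rog") {
  if (is.null(df) || !nrow(df)) return("<p>(empty)</p>")
  head <- paste0("<tr>", paste0("<th>", .html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(df)), function(i) {
    style <- if (rog_col %in% names(df) && df[[rog_col]][i] %in%
                 names(.rog_color))
      sprintf(" style=\"color:%s\"", .rog_color[df[[rog_col]][i]]) else ""
    cells <- vapply(df[i, ], function(x)
      .html_escape(format(x, digits = 4)), "")
    paste0("<tr", style, ">", paste0("<td>", cells, "</td>", collapse = ""),
           "</tr>")
  }, "")
  paste0("<table border=\"1\" cellspacing=\"0\" cellpadding=\"2\">", head,
         paste(body, collapse = "\n"), "</table>")
}

.render_html <- function(report) {
  s <- report$summary
  c("<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    sprintf("<title>Validation report: %s</title></head><body>",
            .html_escape(s$name)),
    sprintf("<h1>Validation report: %s</h1>", .html_escape(s$name)),
    sprintf("<p>Molecule ROG: <b style=\"color:%s\">%s</b>; residues green/orange/red: %.1f%% / %.1f%% / %.1f%% over range %s</p>",
            .rog_color[s$molecule_rog], s$molecule_rog, s$pct_green,
            s$pct_orange, s$pct_red, .html_escape(s$range)),
    if (!is.na(s$rmsd_to_mean))
      sprintf("<p>Backbone RMSD to mean: %.2f &#177; %.2f &#8491; (closest model %d)</p>",
              s$rmsd_to_mean, s$rmsd_sd, s$closest_model) else "",
    sprintf("<p>%d distance / %d dihedral restraints; %d duplicates; NOE completeness %s</p>",
            s$n_distance_restraints, s$n_dihedral_restraints,
            s$n_duplicates,
            if (is.na(s$noe_completeness)) "n/a"
            else sprintf("%.1f%%", s$noe_completeness)),
    "<h2>Per-residue scores</h2>", .html_table(report$per_residue),
    "<h2>Validation records</h2>", .html_table(report$records),
    "<h2>Salt bridges</h2>",
    .html_table(report$interactions$salt_bridges, rog_col = ""),
    "</body></html>")
}
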