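# shortest decimal string that round-trips the double exactly
.num_str <- function(x) {
  for (d in c(6, 15, 17)) {
    s <- sprintf("%.*g", d, x)
    if (as.numeric(s) == x) return(s)
  }
  s
}

#' Render an interaction table
#'
#' Lays the stable interactions out with one column per ligand residue of the
#' peptide window (headers like `pY114`, `R115`), a region band row
#' (flank/I/II/III), and the interacting receptor residues listed under their
#' ligand column as `"K591 s-s"` cells. The `"text"` format is the
#' human-readable fixed-width layout; the `"tsv"` format is tab-separated
#' with `#`-prefixed header lines and extends each cell with the exact
#' occupancy (as an on-frame fraction) and the contact kind so that
#' [parse_interaction_table()] reconstructs the records exactly.
#'
#' @param table An `interaction_table` from [stable_interactions()].
#' @param format `"text"` or `"tsv"`.
#' @return Character vector of output lines.
#' @export
render_table <- function(table, format = c("text", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "interaction_table"))
  peptide <- attr(table, "peptide")
  nf <- attr(table, "n_frames")
  threshold <- attr(table, "threshold")
  win <- peptide$residues
  col_labels <- .ligand_label(win$resname, win$resnum)
  rec_chains <- unique(table$receptor_chain)
  qualify <- length(rec_chains) > 1
  cells <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    rs <- table %>%
      filter(.data$ligand_resnum == win$resnum[i]) %>%
      arrange(.data$receptor_resnum)
    if (nrow(rs) == 0) {
      cells[[i]] <- character(0)
      next
    }
    lab <- .receptor_label(rs$receptor_resname, rs$receptor_resnum)
    if (qualify) lab <- paste0(rs$receptor_chain, ":", lab)
    cells[[i]] <- if (format == "tsv") {
      paste(lab, rs$class_label, paste0(rs$n_on, "/", nf), rs$kind)
    } else {
      paste(lab, rs$class_label)
    }
  }
  depth <- max(c(0L, lengths(cells)))
  grid <- vapply(cells, function(cc) c(cc, rep("", depth - length(cc))),
                 character(depth))
  if (depth == 1) grid <- matrix(grid, nrow = 1)
  if (format == "tsv") {
    hdr <- c("# mdcontacts interaction table",
             paste0("# py_number=", peptide$py_number,
                    " sequence=", peptide$sequence,
                    " chain=", peptide$chain,
                    if (length(rec_chains) == 1)
                      paste0(" receptor_chain=", rec_chains) else "",
                    " n_frames=", nf,
                    " threshold=", .num_str(threshold)),
             paste(c("# region", win$region), collapse = "\t"),
             paste(c("# residue", col_labels), collapse = "\t"))
    body <- if (depth == 0) character(0) else
      apply(grid, 1, function(r) paste(ifelse(r == "", ".", r),
                                       collapse = "\t"))
    return(c(hdr, body))
  }
  widths <- pmax(nchar(col_labels),
                 if (depth == 0) 0 else apply(grid, 2, function(cc)
                   max(nchar(cc))))
  pad <- function(v) paste(mapply(formatC, v, width = widths,
                                  MoreArgs = list(flag = "-")),
                           collapse = "  ")
  lines <- c(paste0("Region   ", pad(win$region)),
             paste0("Ligand   ", pad(col_labels)))
  if (depth > 0) {
    for (r in seq_len(depth)) {
      lines <- c(lines, paste0("         ", pad(grid[r, ])))
    }
  }
  trimws(lines, which = "right")
}

#' Write an interaction table to a file
#'
#' @inheritParams render_table
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(table, path, format = c("text", "tsv")) {
  writeLines(render_table(table, format), path)
  invisible(path)
}

#' Parse a TSV interaction table back into records
#'
#' Inverse of `render_table(..., format = "tsv")`: reconstructs the
#' `interaction_table` (records, peptide, threshold, frame count) from the
#' rendered file, losslessly.
#'
#' @param path File path, or a character vector of lines.
#' @return An `interaction_table` tibble.
#' @export
parse_interaction_table <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  meta_line <- grep("^# py_number=", lines, value = TRUE)
  if (length(meta_line) != 1) abort("not a mdcontacts interaction tsv")
  kv <- strsplit(trimws(sub("^# ", "", meta_line)), " ")[[1]]
  meta <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  peptide <- make_peptide(as.integer(meta[["py_number"]]),
                          meta[["sequence"]], meta[["chain"]])
  nf <- as.integer(meta[["n_frames"]])
  threshold <- as.numeric(meta[["threshold"]])
  res_line <- grep("^# residue\t", lines, value = TRUE)
  labels <- strsplit(res_line, "\t")[[1]][-1]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  recs <- list()
  rev_map <- setNames(names(.aa_codes), .aa_codes)
  for (row in body) {
    parts <- strsplit(row, "\t")[[1]]
    for (j in seq_along(parts)) {
      cell <- parts[j]
      if (cell == "." || cell == "") next
      tok <- strsplit(cell, " ")[[1]]
      lab <- tok[1]
      chain <- if (grepl(":", lab)) sub(":.*$", "", lab) else
        meta[["receptor_chain"]]
      lab <- sub("^[^:]*:", "", lab)
      one <- sub("[0-9]+$", "", lab)
      rn <- as.integer(sub("^[^0-9]*", "", lab))
      resname3 <- if (one == "pY") "PTR" else unname(.aa_codes[one])
      frac <- as.integer(strsplit(tok[3], "/")[[1]])
      recs[[length(recs) + 1]] <- tibble(
        ligand_resnum = peptide$residues$resnum[j],
        receptor_chain = chain, receptor_resnum = rn,
        receptor_resname = resname3, kind = tok[4], class_label = tok[2],
        n_on = frac[1])
    }
  }
  records <- if (length(recs) == 0) {
    tibble(ligand_resnum = integer(), receptor_chain = character(),
           receptor_resnum = integer(), receptor_resname = character(),
           kind = character(), class_label = character(), n_on = integer())
  } else bind_rows(recs)
  records <- records %>%
    left_join(peptide$residues %>%
                select("resnum", ligand_resname = "resname",
                       "offset", "region"),
              by = c(ligand_resnum = "resnum")) %>%
    mutate(ligand_chain = peptide$chain,
           occupancy = .data$n_on / nf,
           lig_side = sub("-.*$", "", .data$class_label),
           rec_side = sub("^[^-]*-", "", .data$class_label)) %>%
    arrange(.data$ligand_resnum, .data$receptor_resnum) %>%
    select("ligand_chain", "ligand_resnum", "ligand_resname", "offset",
           "region", "receptor_chain", "receptor_resnum", "receptor_resname",
           "kind", "class_label", "lig_side", "rec_side", "n_on", "occupancy")
  structure(records, peptide = peptide, threshold = threshold, n_frames = nf,
            class = c("interaction_table", class(tibble())))
}

#' Per-region summary of an interaction table
#'
#' Counts the stable interaction records in interface regions I, II and III
#' (flank records, if any, are listed separately and excluded from the
#' region counts), plus a per-ligand-residue breakdown over the window.
#'
#' @param table An `interaction_table`.
#' @return A `region_summary` list with `counts` (tibble `region`, `n`) and
#'   `per_residue` (tibble `offset`, `label`, `n`).
#' @export
region_summary <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  peptide <- attr(table, "peptide")
  counts <- tibble(region = c("I", "II", "III")) %>%
    left_join(table %>% filter(.data$region != "flank") %>%
                dplyr::count(.data$region), by = "region") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  win <- peptide$residues
  per_residue <- win %>%
    mutate(label = .ligand_label(.data$resname, .data$resnum)) %>%
    left_join(table %>% dplyr::count(.data$offset), by = "offset") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) %>%
    select("offset", "label", "region", "n")
  structure(list(counts = counts, per_residue = per_residue,
                 n_flank = sum(table$region == "flank")),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat("<region_summary>\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  region %-3s %d record(s)\n",
                x$counts$region[i], x$counts$n[i]))
  }
  if (x$n_flank > 0) cat(sprintf("  flank      %d record(s)\n", x$n_flank))
  invisible(x)
}
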