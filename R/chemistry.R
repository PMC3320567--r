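#' Atom-role chemistry table
#'
#' The table that drives every classification in the package: for each
#' supported residue (20 standard amino acids, phosphotyrosine `PTR`, and the
#' `ACE`/`NME` capping groups) it lists every heavy atom with a backbone flag
#' (main-chain vs side-chain) and a polarity class. Polarity is one of
#' `donor`, `acceptor`, `donor_and_acceptor`, `charged_positive`,
#' `charged_negative`, `apolar`, `other_polar`.
#'
#' Apolar atoms are the carbon and sulfur atoms not covalently bonded to a
#' nitrogen or oxygen within the residue's standard topology; this is the
#' package's operational definition of the "hydrophobic atoms" of a side
#' chain. Arg NE counts as `charged_positive` (delocalised guanidinium);
#' Cys SG and Met SD are apolar; His ND1/NE2 are `donor_and_acceptor` by
#' default and only become cationic under the `protonated_his` detection
#' switch; the PTR phosphate oxygens (`O1P`/`O2P`/`O3P`, `OP1`-style aliases,
#' and the bridging `OH`) are `charged_negative`.
#'
#' @param file Optional path to a user-supplied replacement table (TSV with
#'   columns `resname`, `atomname`, `backbone`, `polarity`). Defaults to the
#'   table shipped with the package.
#' @return A tibble with columns `resname`, `atomname`, `backbone`,
#'   `polarity`.
#' @export
#' @examples
#' chemistry_table()
chemistry_table <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.chem_cache$table)) return(.chem_cache$table)
    file <- system.file("extdata", "atom_roles.tsv", package = "mdcontacts",
                        mustWork = TRUE)
    tab <- .read_chem(file)
    .chem_cache$table <- tab
    return(tab)
  }
  .read_chem(file)
}

.chem_cache <- new.env(parent = emptyenv())

.read_chem <- function(file) {
  tab <- readr::read_tsv(file, show_col_types = FALSE,
                         col_types = readr::cols(
                           resname = readr::col_character(),
                           atomname = readr::col_character(),
                           backbone = readr::col_logical(),
                           polarity = readr::col_character()))
  bad <- setdiff(unique(tab$polarity), .polarities)
  if (length(bad) > 0) {
    abort(paste0("unknown polarity class(es) in chemistry table: ",
                 paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(tab[, c("resname", "atomname")]) > 0) {
    abort("duplicated (resname, atomname) entries in chemistry table")
  }
  tab
}

.polarities <- c("donor", "acceptor", "donor_and_acceptor", "charged_positive",
                 "charged_negative", "apolar", "other_polar")

.backbone_h <- c("H", "H1", "H2", "H3", "HA", "HA2", "HA3")

#' Classify an atom as main-chain/side-chain and by polarity
#'
#' Deterministic lookup of an atom's role from the chemistry table. Hydrogens
#' are accepted (role `other_polar`; backbone for the amide/alpha hydrogens
#' `H`, `HA`, `HA2`, `HA3` and N-terminal `H1`-`H3`) but carry no
#' donor/acceptor semantics of their own. Unknown residue or heavy-atom names
#' are an error, never a silent fallback.
#'
#' @param name3 Residue code(s), e.g. `"LYS"`, `"PTR"`.
#' @param atom_name Atom name(s), e.g. `"NZ"`, `"O1P"`. Recycled against
#'   `name3`.
#' @param chemistry Chemistry table, see [chemistry_table()].
#' @return A tibble with one row per input: `resname`, `atomname`,
#'   `backbone` (TRUE = main chain), `polarity`.
#' @export
#' @examples
#' atom_role("LYS", "NZ")
#' atom_role("PTR", c("O1P", "CB"))
atom_role <- function(name3, atom_name, chemistry = chemistry_table()) {
  n <- max(length(name3), length(atom_name))
  q <- tibble(resname = rep_len(as.character(name3), n),
              atomname = rep_len(as.character(atom_name), n))
  unknown_res <- setdiff(unique(q$resname), unique(chemistry$resname))
  if (length(unknown_res) > 0) {
    abort(paste0("unsupported residue(s): ", paste(unknown_res, collapse = ", ")))
  }
  is_h <- .element_of(q$atomname) == "H"
  out <- left_join(q, chemistry, by = c("resname", "atomname"))
  out$backbone[is_h] <- q$atomname[is_h] %in% .backbone_h
  out$polarity[is_h] <- "other_polar"
  miss <- which(is.na(out$polarity))
  if (length(miss) > 0) {
    first <- miss[1]
    abort(paste0("unknown atom name ", q$atomname[first], " for residue ",
                 q$resname[first]))
  }
  out
}

#' Does a residue's side chain contain any polar heavy atom?
#'
#' TRUE when the side chain has at least one non-apolar heavy atom. This is
#' the gate for the `hs` classification: a contact may be labelled
#' "hydrophobic-only side chain" only for residues whose side chain also has
#' a polar part; fully apolar side chains (Ile, Leu, Val, Ala, Cys, Met, Phe)
#' always report as `s`.
#'
#' @inheritParams atom_role
#' @return Logical vector along `name3`.
#' @export
#' @examples
#' sidechain_has_polar(c("GLN", "ILE", "PTR"))
sidechain_has_polar <- function(name3, chemistry = chemistry_table()) {
  name3 <- as.character(name3)
  unknown <- setdiff(unique(name3), unique(chemistry$resname))
  if (length(unknown) > 0) {
    abort(paste0("unsupported residue(s): ", paste(unknown, collapse = ", ")))
  }
  polar_sc <- chemistry %>%
    filter(!.data$backbone, .data$polarity != "apolar") %>%
    pull("resname") %>%
    unique()
  name3 %in% polar_sc
}

# Derived role flags used by the detectors. protonated_his promotes His
# ND1/NE2 to charged_positive before flags are computed.
.role_flags <- function(roles, protonated_his = FALSE) {
  pol <- roles$polarity
  if (protonated_his) {
    pol[roles$resname == "HIS" & roles$atomname %in% c("ND1", "NE2")] <-
      "charged_positive"
  }
  elem <- .element_of(roles$atomname)
  roles$polarity <- pol
  roles$is_donor <- pol %in% c("donor", "donor_and_acceptor") |
    (pol == "charged_positive" & elem == "N")
  roles$is_acceptor <- pol %in% c("acceptor", "donor_and_acceptor") |
    (pol == "charged_negative" & elem == "O")
  roles$is_cation_n <- pol == "charged_positive" & elem == "N"
  roles$is_anion_o <- pol == "charged_negative" & elem == "O"
  roles$is_apolar <- pol == "apolar"
  roles
}

# Element symbol from an atom name: strip leading digits, take the first
# alphabetic character ("O1P" -> O, "1HG1" -> H, "NZ" -> N).
.element_of <- function(atomname) {
  stripped <- sub("^[0-9]+", "", atomname)
  toupper(substr(stripped, 1, 1))
}

# m/s/hs side token for a set of participating atoms of one residue.
# Precedence: any polar side-chain atom -> "s"; otherwise any side-chain atom
# -> "hs" if the side chain has a polar part, else "s"; otherwise "m".
.side_token <- function(any_sc_polar, any_sc, has_polar_sc) {
  dplyr::case_when(
    any_sc_polar ~ "s",
    any_sc & has_polar_sc ~ "hs",
    any_sc ~ "s",
    TRUE ~ "m"
  )
}
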