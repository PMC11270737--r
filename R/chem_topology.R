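#' Canonical p53 regulatory-domain construct (residues 351-393)
#'
#' One-letter sequence of the 43-residue C-terminal construct analysed
#' throughout the package: the regulatory domain plus the five preceding
#' tetramerization-domain residues (author numbering 351-393, human p53,
#' UniProt P04637).
#'
#' @return A single string of 43 one-letter amino-acid codes.
#' @export
#' @examples
#' nchar(reg_sequence())  # 43
reg_sequence <- function() {
  "KDAQAGKEPGGSRAHSSHLKSKKGQSTSRHKKLMFKTEGPDSD"
}

#' Experimentally observed phosphosites of the regulatory domain
#'
#' Author residue numbers of the seven serine/threonine phosphorylation
#' sites carried by the fully phosphorylated construct.
#'
#' @return Integer vector of author residue numbers.
#' @export
reg_phosphosites <- function() {
  c(366L, 371L, 376L, 377L, 378L, 387L, 392L)
}

# Side-chain formal charges at physiological pH (His handled separately).
.side_charge <- c(K = 1L, R = 1L, D = -1L, E = -1L)

# Charged-atom sets used for salt-bridge group definitions (standard PDB
# atom naming; phospho groups get the phosphate oxygens plus the ester O).
.charged_atoms <- list(
  K = "NZ",
  R = c("NE", "NH1", "NH2"),
  D = c("OD1", "OD2"),
  E = c("OE1", "OE2"),
  pS = c("O1P", "O2P", "O3P", "OG"),
  pT = c("O1P", "O2P", "O3P", "OG1")
)

.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

#' Build a topology from a one-letter sequence
#'
#' Parses a sequence into a residue table with author numbering, phospho
#' flags and formal side-chain charges.  Phosphosites must name Ser/Thr
#' positions inside the numbering range.
#'
#' @param seq One-letter amino-acid string (e.g. [reg_sequence()]).
#' @param first_author_number Author number of the first residue
#'   (default 351, the construct convention).
#' @param phosphosites Integer vector of author residue numbers carrying a
#'   phosphate.
#' @param phospho_charge Formal charge per phosphate group.  The default -1
#'   models the monoanionic phosphate (three available oxygen atoms and one
#'   protic hydrogen).
#' @param his_protonation `"neutral"` (physiological-pH default) or
#'   `"protonated"` (+1 per His); both bookkeepings are in use for this
#'   construct, see [formal_net_charge()].
#' @param termini_model `"zwitterionic"` (free NH3+/COO-, net zero combined)
#'   or `"capped"`.
#' @return An object of class `reg_topology`: a residue data frame
#'   (`author_number`, `code`, `is_phosphorylated`, `formal_side_charge`)
#'   with the model options as attributes.
#' @export
#' @examples
#' top <- parse_sequence(reg_sequence(), 351, reg_phosphosites())
#' sum(top$is_phosphorylated)  # 7
parse_sequence <- function(seq, first_author_number = 351L,
                           phosphosites = integer(),
                           phospho_charge = -1L,
                           his_protonation = c("neutral", "protonated"),
                           termini_model = c("zwitterionic", "capped")) {
  his_protonation <- match.arg(his_protonation)
  termini_model <- match.arg(termini_model)
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  codes <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(codes, .aa1)
  if (length(bad) > 0L)
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  n <- length(codes)
  author <- seq.int(first_author_number, length.out = n)
  phosphosites <- as.integer(phosphosites)
  if (length(phosphosites) > 0L) {
    out <- setdiff(phosphosites, author)
    if (length(out) > 0L)
      stop("phosphosite(s) outside numbering range ",
           author[1L], "-", author[n], ": ", paste(out, collapse = ", "))
    at <- match(phosphosites, author)
    nonst <- !(codes[at] %in% c("S", "T"))
    if (any(nonst))
      stop("phosphosite on non-Ser/Thr residue: ",
           paste0(codes[at[nonst]], phosphosites[nonst], collapse = ", "))
  }
  res <- data.frame(
    author_number = author,
    code = codes,
    is_phosphorylated = author %in% phosphosites,
    formal_side_charge = unname(ifelse(codes %in% names(.side_charge),
                                       .side_charge[codes], 0L)),
    stringsAsFactors = FALSE
  )
  structure(res,
            class = c("reg_topology", "data.frame"),
            phospho_charge = as.integer(phospho_charge),
            his_protonation = his_protonation,
            termini_model = termini_model)
}

#' @export
print.reg_topology <- function(x, ...) {
  cat(sprintf("reg_topology: %d residues (%d-%d), %d phosphosite(s), His %s, termini %s\n",
              nrow(x), x$author_number[1L], x$author_number[nrow(x)],
              sum(x$is_phosphorylated), attr(x, "his_protonation"),
              attr(x, "termini_model")))
  invisible(x)
}

#' Charged side-chain groups of a topology
#'
#' One group per Lys/Arg/Asp/Glu side chain and per phosphosite, each with
#' its charged-atom name set and sign.  These are the "charged species"
#' whose pairwise contacts define salt bridges; His is never counted as a
#' species even when protonated, so the signed sum here can differ from
#' [formal_net_charge()] by the His and termini contributions.
#'
#' @param top A `reg_topology`.
#' @param include_termini If `TRUE`, append the N-terminus (atom `N`, +1)
#'   and C-terminus (atoms `O`/`OXT`, -1) as two extra groups.
#' @return A data frame with columns `author_number`, `code`, `label`
#'   (e.g. `"K351"`, `"pS392"`), `sign`, and a list-column `atoms`.
#' @export
#' @examples
#' g <- charged_groups(parse_sequence(reg_sequence(), 351))
#' nrow(g); sum(g$sign)  # 15 groups, net +5
charged_groups <- function(top, include_termini = FALSE) {
  stopifnot(inherits(top, "reg_topology"))
  pq <- attr(top, "phospho_charge")
  rows <- list()
  for (i in seq_len(nrow(top))) {
    code <- top$code[i]
    num <- top$author_number[i]
    if (top$is_phosphorylated[i]) {
      key <- paste0("p", code)
      rows[[length(rows) + 1L]] <- list(
        author_number = num, code = code, label = paste0("p", code, num),
        sign = as.integer(pq), atoms = .charged_atoms[[key]])
    } else if (code %in% names(.side_charge)) {
      rows[[length(rows) + 1L]] <- list(
        author_number = num, code = code, label = paste0(code, num),
        sign = .side_charge[[code]], atoms = .charged_atoms[[code]])
    }
  }
  if (include_termini) {
    n <- nrow(top)
    rows[[length(rows) + 1L]] <- list(
      author_number = top$author_number[1L], code = top$code[1L],
      label = "Nterm", sign = 1L, atoms = "N")
    rows[[length(rows) + 1L]] <- list(
      author_number = top$author_number[n], code = top$code[n],
      label = "Cterm", sign = -1L, atoms = c("O", "OXT"))
  }
  out <- data.frame(
    author_number = vapply(rows, `[[`, integer(1), "author_number"),
    code = vapply(rows, `[[`, character(1), "code"),
    label = vapply(rows, `[[`, character(1), "label"),
    sign = vapply(rows, `[[`, integer(1), "sign"),
    stringsAsFactors = FALSE
  )
  out$atoms <- lapply(rows, `[[`, "atoms")
  out
}

#' Formal net charge of a construct
#'
#' Sum of side-chain formal charges, phosphate charges, His protonation
#' (+1 per His under the `"protonated"` convention) and termini
#' (zwitterionic termini are net zero).  For the 43-residue regulatory
#' construct this reproduces the +8 / +7 / +1 bookkeeping of the
#' unmodified, singly and fully phosphorylated states under protonated-His
#' accounting, and +5 for the charged side chains alone under the neutral
#' default.
#'
#' @param top A `reg_topology`.
#' @return Integer net charge.
#' @export
formal_net_charge <- function(top) {
  stopifnot(inherits(top, "reg_topology"))
  q <- sum(top$formal_side_charge)
  if (attr(top, "his_protonation") == "protonated")
    q <- q + sum(top$code == "H")
  q <- q + sum(top$is_phosphorylated) * attr(top, "phospho_charge")
  # zwitterionic termini contribute +1 - 1 = 0; capped termini contribute 0
  as.integer(q)
}

#' Neutralizing counterion count
#'
#' Number of monovalent counterions of the opposite sign needed to
#' neutralize a net charge (e.g. +8 needs eight chloride ions).
#'
#' @param net Integer net charge.
#' @return Named integer: number of ions, named `"anions"` for positive
#'   `net`, `"cations"` for negative, `"none"` for zero.
#' @export
counterion_count <- function(net) {
  net <- as.integer(net)
  n <- abs(net)
  names(n) <- if (net > 0L) "anions" else if (net < 0L) "cations" else "none"
  n
}

#' Read the first sequence from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return One-letter sequence string.
#' @export
read_fasta_sequence <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA header in ", path)
  end <- if (length(hdr) > 1L) hdr[2L] - 1L else length(lines)
  paste(lines[(hdr[1L] + 1L):end], collapse = "")
}

#' Build a topology from a JSON configuration block
#'
#' Accepts keys `sequence`, `first_residue`, `phosphosites`,
#' `phospho_charge`, `his_protonation`, `termini_model`.
#'
#' @param config A list (parsed JSON) or path to a JSON file.
#' @return A `reg_topology`.
#' @export
topology_from_config <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  parse_sequence(
    seq = config$sequence,
    first_author_number = config$first_residue %||% 351L,
    phosphosites = config$phosphosites %||% integer(),
    phospho_charge = config$phospho_charge %||% -1L,
    his_protonation = config$his_protonation %||% "neutral",
    termini_model = config$termini_model %||% "zwitterionic"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
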