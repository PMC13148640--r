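## Extant Phylogenetic Bracket muscle reconstruction: unordered-parsimony
## ancestral states over a phylogeny of saurians scored for osteological
## correlates of muscle attachments, plus Witmer inference levels.

#' Parse a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that validates tip labels are
#' unique and returns a rooted `phylo` object; polytomies are preserved.
#'
#' @param text Newick string (or a file path via `file`).
#' @param file optional path to a Newick file.
#' @return an `ape` `phylo` tree.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) ape::read.tree(file)
          else ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse error (unbalanced parentheses?)")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Parse a character matrix (CSV or NEXUS subset)
#'
#' Reads a taxa x characters matrix of small integer state codes.
#' Missing entries are "?" (any state) and inapplicable entries are "-"
#' (excluded from change counts, treated as missing for optimisation but
#' flagged separately). CSV input: first column taxon names, remaining
#' columns characters. NEXUS input: a CHARACTERS/DATA block MATRIX with
#' single-digit states.
#'
#' @param file path to CSV or NEXUS file (format sniffed from content).
#' @param tree optional `phylo`; taxon names are checked against its
#'   tips, erroring with the offenders listed.
#' @return object of class `character_matrix`: integer matrix (NA =
#'   missing) with attribute `inapplicable` (logical matrix).
#' @export
parse_character_matrix <- function(file, tree = NULL) {
  first <- readLines(file, n = 1L, warn = FALSE)
  raw <- if (grepl("^#NEXUS", first, ignore.case = TRUE))
    parse_nexus_matrix(file) else parse_csv_matrix(file)
  m <- raw$states
  inapp <- raw$inapplicable
  if (!is.null(tree)) {
    missing_taxa <- setdiff(tree$tip.label, rownames(m))
    extra <- setdiff(rownames(m), tree$tip.label)
    if (length(missing_taxa) > 0 || length(extra) > 0)
      stop("taxon/tree name mismatch; missing from matrix: ",
           paste(missing_taxa, collapse = ", "),
           "; not in tree: ", paste(extra, collapse = ", "))
  }
  structure(m, inapplicable = inapp, class = "character_matrix")
}

tokenise_states <- function(cells, taxa) {
  n_char <- length(cells[[1]])
  m <- matrix(NA_integer_, length(taxa), n_char,
              dimnames = list(taxa, NULL))
  inapp <- matrix(FALSE, length(taxa), n_char, dimnames = list(taxa, NULL))
  for (i in seq_along(taxa)) {
    row <- cells[[i]]
    if (length(row) != n_char)
      stop(sprintf("taxon '%s': %d states, expected %d", taxa[i],
                   length(row), n_char))
    num <- suppressWarnings(as.integer(row))
    m[i, ] <- num
    inapp[i, row == "-"] <- TRUE
    bad <- is.na(num) & !(row %in% c("?", "-"))
    if (any(bad))
      stop(sprintf("taxon '%s': unrecognised state(s) %s", taxa[i],
                   paste(unique(row[bad]), collapse = ", ")))
  }
  list(states = m, inapplicable = inapp)
}

parse_csv_matrix <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  taxa <- df[[1]]
  cells <- lapply(seq_len(nrow(df)), function(i)
    trimws(as.character(unlist(df[i, -1]))))
  tokenise_states(cells, taxa)
}

parse_nexus_matrix <- function(file) {
  lines <- readLines(file, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  mat <- regmatches(txt, regexpr("(?is)matrix\\s.*?;", txt, perl = TRUE))
  if (length(mat) == 0) stop("no MATRIX block found in NEXUS file")
  body <- sub("(?is)^matrix\\s", "", mat, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  rows <- strsplit(trimws(body), "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows) & !grepl("^\\[", rows)]
  taxa <- character(0); cells <- list()
  for (r in rows) {
    parts <- strsplit(r, "\\s+")[[1]]
    if (length(parts) < 2) stop("malformed NEXUS matrix row: ", r)
    taxa <- c(taxa, gsub("^'|'$", "", parts[1]))
    cells[[length(cells) + 1L]] <-
      strsplit(paste(parts[-1], collapse = ""), "")[[1]]
  }
  tokenise_states(cells, taxa)
}

#' Minimum-change (Fitch) ancestral-state optimisation
#'
#' Unordered maximum-parsimony ancestral states for every character on a
#' rooted tree, by unit-cost dynamic programming (a Sankoff down-pass
#' giving per-node per-state subtree costs, then an up-pass giving
#' outside costs). For each internal node and character the full set of
#' most-parsimonious-reconstruction (MPR) states is returned; a singleton
#' set is an unambiguous reconstruction, and only those should be read as
#' firm ancestral conditions. Missing ("?") and inapplicable ("-") codes
#' contribute no cost. All-missing characters are flagged and skipped.
#'
#' @param tree rooted `phylo` tree.
#' @param matrix a `character_matrix` (or plain integer matrix, rows
#'   named by taxa).
#' @return list of class `ancestral_state_map`: `node_states` (list per
#'   character of list per node of integer state sets; nodes indexed as
#'   in `ape`, n_tips + 1 is the root), `changes` (minimum change count
#'   per character; NA for skipped), `skipped` (indices of all-missing
#'   characters).
#' @export
fitch_optimize <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"))
  m <- unclass(matrix)
  if (is.null(rownames(m))) stop("matrix must have taxon rownames")
  if (!all(tree$tip.label %in% rownames(m)))
    stop("matrix lacks taxa: ",
         paste(setdiff(tree$tip.label, rownames(m)), collapse = ", "))
  m <- m[tree$tip.label, , drop = FALSE]
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  edge <- tree$edge
  children_of <- split(edge[, 2], edge[, 1])
  postorder <- rev(topo_node_order(tree))
  preorder <- topo_node_order(tree)
  n_char <- ncol(m)
  changes <- rep(NA_real_, n_char)
  node_states <- vector("list", n_char)
  skipped <- integer(0)
  for (ch in seq_len(n_char)) {
    obs <- m[, ch]
    states <- sort(unique(obs[!is.na(obs)]))
    if (length(states) == 0) { skipped <- c(skipped, ch); next }
    ns <- length(states)
    big <- 1e9
    # down-pass subtree costs
    cost <- matrix(0, n_node, ns)
    for (tip in seq_len(n_tip)) {
      if (!is.na(obs[tip])) {
        cost[tip, ] <- big
        cost[tip, match(obs[tip], states)] <- 0
      }
    }
    for (v in postorder) {
      if (v <= n_tip) next
      acc <- numeric(ns)
      for (u in children_of[[as.character(v)]]) {
        cu <- cost[u, ]
        acc <- acc + pmin(cu, min(cu) + 1)
      }
      cost[v, ] <- acc
    }
    total <- min(cost[root, ])
    changes[ch] <- total
    # up-pass outside costs
    out <- matrix(0, n_node, ns)
    for (v in preorder) {
      kids <- children_of[[as.character(v)]]
      if (is.null(kids)) next
      for (u in kids) {
        sib_cost <- numeric(ns)
        for (w in setdiff(kids, u)) {
          cw <- cost[w, ]
          sib_cost <- sib_cost + pmin(cw, min(cw) + 1)
        }
        base <- out[v, ] + sib_cost   # cost of everything except subtree u,
                                      # as a function of v's state
        out[u, ] <- vapply(seq_len(ns), function(s)
          min(base + as.numeric(seq_len(ns) != s)), numeric(1))
      }
    }
    sets <- vector("list", n_node)
    for (v in seq_len(n_node)) {
      tot_v <- cost[v, ] + out[v, ]
      sets[[v]] <- states[tot_v <= total + 1e-9]
    }
    node_states[[ch]] <- sets
  }
  structure(list(node_states = node_states, changes = changes,
                 skipped = skipped, tree = tree,
                 n_tips = n_tip),
            class = "ancestral_state_map")
}

topo_node_order <- function(tree) {
  # preorder from root
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- root
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    kids <- children_of[[as.character(v)]]
    if (!is.null(kids)) stack <- c(stack, kids)
  }
  out
}

#' Witmer inference level for a reconstructed attachment
#'
#' Combines the parsimony reconstruction at the focal node with the
#' presence of an osteological correlate on the fossil: an unambiguous
#' (singleton) reconstructed state agreeing with the extant bracket gives
#' Level I, an ambiguous reconstruction Level II, and a prime (I' / II')
#' marks the absence of a clear osteological correlate on the fossil.
#' Unknown bracket states propagate to II'.
#'
#' @param node_state_set integer vector of reconstructed states at the
#'   focal taxon's ancestral node.
#' @param bracket_states optional integer vector of the extant bracket
#'   taxa's states (used only for the rationale string; NA = unknown).
#' @param correlate_present logical; is an osteological correlate visible
#'   on the fossil?
#' @return list of class `inference_level` with `level` ("I", "I'",
#'   "II", "II'") and `rationale`.
#' @export
epb_level <- function(node_state_set, bracket_states = NULL,
                      correlate_present = TRUE) {
  unknown_bracket <- !is.null(bracket_states) && all(is.na(bracket_states))
  singleton <- length(node_state_set) == 1 && !unknown_bracket
  base <- if (singleton) "I" else "II"
  level <- if (correlate_present) base else paste0(base, "'")
  rationale <- paste0(
    if (singleton) "unambiguous ancestral state"
    else if (unknown_bracket) "bracket states unknown"
    else "ambiguous ancestral state (MPR set size > 1)",
    if (correlate_present) "; osteological correlate present"
    else "; no clear osteological correlate")
  structure(list(level = level, rationale = rationale),
            class = "inference_level")
}

#' Build a muscle reconstruction map
#'
#' One row per muscle giving origin, insertion and their inference
#' levels in bracketed table style (e.g. "[I']"), from an attachment
#' dictionary and (optionally) an ancestral-state map whose characters
#' the dictionary references.
#'
#' @param dictionary data.frame with columns `muscle`, `full_name`,
#'   `origin`, `insertion`, `origin_level`, `insertion_level` and
#'   optionally `origin_char`, `insertion_char` (character indices into
#'   the state map).
#' @param state_map optional `ancestral_state_map`; when supplied along
#'   with `focal_node`, levels are recomputed from the reconstruction
#'   (singleton vs ambiguous) and correlate flags
#'   `origin_correlate`/`insertion_correlate` in the dictionary.
#' @param focal_node node index of the focal taxon's immediate ancestor.
#' @return data.frame of class `muscle_map`.
#' @export
build_muscle_map <- function(dictionary, state_map = NULL,
                             focal_node = NULL) {
  need <- c("muscle", "origin", "insertion", "origin_level",
            "insertion_level")
  if (!all(need %in% names(dictionary)))
    stop("dictionary lacks columns: ",
         paste(setdiff(need, names(dictionary)), collapse = ", "))
  out <- dictionary
  if (!is.null(state_map) && !is.null(focal_node)) {
    for (side in c("origin", "insertion")) {
      chcol <- paste0(side, "_char")
      ccol <- paste0(side, "_correlate")
      if (!chcol %in% names(dictionary)) next
      for (i in seq_len(nrow(out))) {
        ch <- dictionary[[chcol]][i]
        if (is.na(ch)) next
        if (ch %in% state_map$skipped || ch > length(state_map$node_states))
          stop(sprintf("muscle '%s': unmapped character %d",
                       dictionary$muscle[i], ch))
        set <- state_map$node_states[[ch]][[focal_node]]
        corr <- if (ccol %in% names(dictionary)) dictionary[[ccol]][i]
                else TRUE
        out[[paste0(side, "_level")]][i] <-
          epb_level(set, correlate_present = corr)$level
      }
    }
  }
  out$origin_level <- paste0("[", gsub("\\[|\\]", "", out$origin_level), "]")
  out$insertion_level <- paste0("[", gsub("\\[|\\]", "", out$insertion_level), "]")
  class(out) <- c("muscle_map", "data.frame")
  out
}

#' Packaged pelvic-limb muscle dictionary for the focal pseudosuchian
#'
#' The 37 pelvic-limb muscles reconstructed for the focal Triassic
#' pseudosuchian model, with crocodylian-convention acronyms, attachment
#' summaries and published Witmer inference levels (prime = no clear
#' osteological correlate on the fossil).
#'
#' @return data.frame with columns `muscle`, `full_name`, `origin`,
#'   `insertion`, `origin_level`, `insertion_level`.
#' @export
gracilisuchus_muscle_dictionary <- function() {
  rows <- list(
    c("IT1", "M. iliotibialis 1", "craniodorsal iliac rim", "cnemial crest of tibia", "I", "I'"),
    c("IT2", "M. iliotibialis 2", "dorsal iliac rim", "cnemial crest of tibia", "I", "I'"),
    c("IT3", "M. iliotibialis 3", "caudodorsal iliac rim", "cnemial crest of tibia", "I", "I'"),
    c("FMTE", "M. femorotibialis externus", "lateral femoral shaft", "cnemial crest of tibia", "I'", "I'"),
    c("FMTI", "M. femorotibialis internus", "cranial/medial femoral shaft", "cnemial crest of tibia", "I'", "I'"),
    c("AMB", "M. ambiens", "pubic tubercle", "cnemial crest of tibia", "I", "I'"),
    c("ILFB", "M. iliofibularis", "lateral postacetabular ilium", "iliofibular tubercle of fibula", "I", "I"),
    c("IF", "M. iliofemoralis", "lateral ilium above acetabulum", "caudolateral femoral midshaft", "I", "II'"),
    c("PIFI1", "M. puboischiofemoralis internus 1", "ventromedial ilium / puboischiadic plate", "craniomedial proximal femur", "II", "I"),
    c("PIFI2", "M. puboischiofemoralis internus 2", "dorsal vertebrae near preacetabular ilium", "craniolateral proximal femur", "II", "I'"),
    c("PIT", "M. puboischiotibialis", "craniolateral proximal ischial apron", "medial proximal tibia", "II", "I'"),
    c("FTI1", "M. flexor tibialis internus 1", "lateral distal ischial shaft", "medial proximal tibia", "II'", "I'"),
    c("FTI3", "M. flexor tibialis internus 3", "proximolateral ischium", "caudal proximal tibia", "I'", "I'"),
    c("FTE", "M. flexor tibialis externus", "caudoventral postacetabular ilium", "caudal proximal tibia", "I'", "I'"),
    c("PIFE1", "M. puboischiofemoralis externus 1", "cranial pubic apron", "greater trochanter of femur", "II", "I"),
    c("PIFE2", "M. puboischiofemoralis externus 2", "caudal pubic apron", "greater trochanter of femur", "II", "I"),
    c("PIFE3", "M. puboischiofemoralis externus 3", "lateral ischial apron", "greater trochanter of femur", "II", "I"),
    c("ISTR", "M. ischiotrochantericus", "medial ischial apron", "lateral proximal femur", "I", "I"),
    c("CFB", "M. caudofemoralis brevis", "proximal caudals and medial iliac shelf", "proximal fourth trochanter", "I", "I"),
    c("CFL", "M. caudofemoralis longus", "haemal arches / proximal caudal transverse processes", "fourth trochanter of femur", "I", "I"),
    c("ADD1", "M. adductor femoris 1", "craniolateral ischial apron", "caudomedial distal femoral shaft", "I'", "I'"),
    c("ADD2", "M. adductor femoris 2", "caudolateral dorsal ischial shaft", "caudolateral distal femoral shaft", "I'", "I'"),
    c("GI", "M. gastrocnemius internus", "medial cnemial crest of tibia", "calcaneal tuber and plantar aponeurosis", "I'", "II"),
    c("GE", "M. gastrocnemius externus", "caudolateral distal femur", "calcaneal tuber and plantar aponeurosis", "I'", "II"),
    c("EDL", "M. extensor digitorum longus", "lateral cnemial crest and cranial tibial shaft", "proximal metatarsals I-II", "II", "I'"),
    c("EDB", "M. extensor digitorum brevis", "cranial proximal tarsals", "dorsal distal phalanges", "I'", "I"),
    c("TA", "M. tibialis anterior", "craniolateral distal femur and cnemial crest", "craniomedial proximal metatarsals II-IV", "I", "I"),
    c("FDL", "M. flexor digitorum longus", "proximomedial fibular shaft", "flexor tubercles of pedal unguals I-V", "I'", "I"),
    c("FHL", "M. flexor hallucis longus", "caudolateral distal femur and fossa flexoria", "flexor tubercles of pedal unguals I-V", "I'", "I"),
    c("FDB", "M. flexor digitorum brevis", "plantar aponeurosis", "flexor tubercles of pedal unguals I-IV", "I'", "I"),
    c("FHB", "M. flexor hallucis brevis", "distal tarsals and plantar aponeurosis", "plantar metatarsal I and digit 1", "I'", "I'"),
    c("FL", "M. fibularis longus", "lateral fibular shaft", "lateral metatarsal V and calcaneal tuber", "I", "I"),
    c("FB", "M. fibularis brevis", "distal craniolateral fibular shaft", "caudolateral metatarsal V", "I", "I"),
    c("PP1", "M. interosseous cruris", "caudolateral proximal tibial shaft", "caudolateral metatarsal I and tarsals", "I'", "II"),
    c("PP2", "M. pronator profundus", "caudomedial fibular shaft", "caudolateral metatarsal I and tarsals", "I", "II"),
    c("FC", "M. fibulocalcaneus", "caudal distal fibula", "dorsal calcaneal tuber", "I", "II"),
    c("AHD", "M. adductor hallucis dorsalis", "craniolateral distal fibula", "proximodorsal metatarsal I", "I'", "I"))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("muscle", "full_name", "origin", "insertion",
                 "origin_level", "insertion_level")
  df
}
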