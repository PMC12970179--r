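# Regex SMILES tokenizer, vocabulary handling, and a token-stream topology
# scanner that resolves ring closures and branches to atom/bond indices
# (used to align stereo annotations with the parsed heavy-atom graph).

# Atom-level regex: bracket atoms are atomic units; two-letter organic-subset
# halogens before their one-letter prefixes; %nn ring closures before digits.
.smiles_token_regex <- paste0(
  "\\[[^\\]]+\\]|Br|Cl|@@|@|%\\d{2}|",
  "[bcnops]|[BCNOPSFI]|[-=#:/\\\\+~*$]|\\d|\\(|\\)|\\."
)

#' Reserved special tokens
#'
#' Pad, mask, unknown, begin and end markers reserved at the head of every
#' vocabulary (ids 1..5).
#' @export
special_tokens <- c("<pad>", "<mask>", "<unk>", "<bos>", "<eos>")

# frozen seed vocabulary of common organic-chemistry tokens
.seed_vocab <- c(
  "C", "c", "N", "n", "O", "o", "S", "s", "P", "p", "B", "b", "F", "Cl",
  "Br", "I", "=", "#", "-", "+", ":", "/", "\\", ".", "(", ")", "~",
  as.character(0:9), "%10", "%11", "%12",
  "[nH]", "[NH]", "[N+]", "[N-]", "[n+]", "[O-]", "[OH]", "[S+]", "[C@H]",
  "[C@@H]", "[C@]", "[C@@]", "[H]", "[Si]", "[Se]", "[se]", "[P+]", "[B-]"
)

#' Build a token vocabulary
#'
#' Reserved specials first, then a frozen seed vocabulary of common tokens,
#' then any novel tokens found in the corpus (first-seen order).
#'
#' @param corpus_tokens optional character vector (or list) of surface tokens
#'   to extend the seed vocabulary with.
#' @return character vector of class \code{smiles_vocab}; names are ids.
#' @export
build_vocab <- function(corpus_tokens = NULL) {
  extra <- setdiff(unique(unlist(corpus_tokens)), c(special_tokens, .seed_vocab))
  structure(c(special_tokens, .seed_vocab, extra), class = "smiles_vocab")
}

.default_vocab <- NULL
default_vocab <- function() {
  if (is.null(.default_vocab)) build_vocab() else .default_vocab
}

#' Write / read a vocabulary as a token-per-line text file
#' @param vocab a \code{smiles_vocab}.
#' @param path file path.
#' @export
write_vocab <- function(vocab, path) writeLines(unclass(vocab), path)

#' @rdname write_vocab
#' @export
read_vocab <- function(path) structure(readLines(path), class = "smiles_vocab")

#' Tokenize a SMILES string
#'
#' Regex-driven split into bracket atoms, organic-subset atoms, bond symbols,
#' ring-closure digits and branch parentheses. The concatenation of the
#' surface tokens always reproduces the input; characters the regex does not
#' recognize become \code{<unk>} tokens with a warning.
#'
#' @param smiles a single non-empty SMILES string.
#' @param vocab vocabulary used for id lookup (default: built-in).
#' @return object of class \code{text_view}: \code{tokens} (surface strings),
#'   \code{token_ids}, \code{vocab}, \code{smiles}.
#' @export
tokenize_smiles <- function(smiles, vocab = default_vocab()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("empty SMILES string")
  m <- gregexpr(.smiles_token_regex, smiles, perl = TRUE)[[1]]
  toks <- surface <- character(0)
  if (m[1] != -1) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    # fill unmatched gaps with <unk> spans
    pos <- 1L; out <- character(0); surf <- character(0)
    for (k in seq_along(starts)) {
      if (starts[k] > pos) {
        out <- c(out, "<unk>")
        surf <- c(surf, substr(smiles, pos, starts[k] - 1L))
      }
      piece <- substr(smiles, starts[k], starts[k] + lens[k] - 1L)
      out <- c(out, piece); surf <- c(surf, piece)
      pos <- starts[k] + lens[k]
    }
    if (pos <= nchar(smiles)) {
      out <- c(out, "<unk>"); surf <- c(surf, substr(smiles, pos, nchar(smiles)))
    }
    toks <- out; surface <- surf
  } else {
    toks <- "<unk>"; surface <- smiles
  }
  if (any(toks == "<unk>")) {
    warning("unrecognized SMILES span(s) mapped to <unk>: ",
            paste(surface[toks == "<unk>"], collapse = " "))
  }
  ids <- match(toks, vocab)
  ids[is.na(ids)] <- match("<unk>", vocab)
  structure(list(tokens = toks, surface = surface, token_ids = ids,
                 vocab = vocab, smiles = smiles),
            class = "text_view")
}

#' Reassemble a SMILES string from its tokens
#' @param view a \code{text_view}.
#' @return the concatenated surface string.
#' @export
detokenize <- function(view) paste(view$surface, collapse = "")

.is_atom_token <- function(tok) {
  grepl("^\\[", tok) | tok %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                                  "Cl", "Br", "b", "c", "n", "o", "p", "s")
}

# Scan a token stream, resolving branches and ring closures. Returns atom
# count, per-atom chirality ("", "@", "@@"), the token index of each atom,
# and the bond list with any explicit bond symbol (including / and \).
# This is a topology scan for annotation alignment, not a SMILES parser:
# valence, aromaticity and charges still come from the Open Babel backend.
smiles_topology <- function(tokens) {
  n_atom <- 0L
  prev <- NA_integer_
  stack <- integer(0)
  ring_open <- list()        # label -> c(atom, bond-symbol index or "")
  chir <- character(0)
  atom_tok_idx <- integer(0)
  b_from <- b_to <- integer(0); b_sym <- character(0)
  pending <- ""
  for (k in seq_along(tokens)) {
    tok <- tokens[k]
    if (.is_atom_token(tok)) {
      n_atom <- n_atom + 1L
      atom_tok_idx[n_atom] <- k
      ch <- ""
      if (grepl("^\\[", tok)) {
        if (grepl("@@", tok, fixed = TRUE)) ch <- "@@"
        else if (grepl("@", tok, fixed = TRUE)) ch <- "@"
      }
      chir[n_atom] <- ch
      if (!is.na(prev)) {
        b_from <- c(b_from, prev); b_to <- c(b_to, n_atom)
        b_sym <- c(b_sym, pending)
      }
      pending <- ""
      prev <- n_atom
    } else if (tok == "(") {
      stack <- c(stack, prev)
    } else if (tok == ")") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok %in% c("-", "=", "#", ":", "/", "\\", "~")) {
      pending <- tok
    } else if (tok == ".") {
      prev <- NA_integer_; pending <- ""
    } else if (grepl("^%?\\d", tok)) {
      lab <- sub("^%", "", tok)
      if (!is.null(ring_open[[lab]])) {
        op <- ring_open[[lab]]
        sym <- if (nzchar(pending)) pending else op$sym
        b_from <- c(b_from, op$atom); b_to <- c(b_to, prev)
        b_sym <- c(b_sym, sym)
        ring_open[[lab]] <- NULL
        pending <- ""
      } else {
        ring_open[[lab]] <- list(atom = prev, sym = pending)
        pending <- ""
      }
    }
    # <unk>, @, @@ outside brackets: ignored by the scanner
  }
  list(n_atoms = n_atom, chirality = chir, atom_token_idx = atom_tok_idx,
       bonds = data.frame(from = b_from, to = b_to, sym = b_sym,
                          stringsAsFactors = FALSE))
}

# heavy-atom count of a SMILES fragment via the token scanner
smiles_atom_count <- function(smiles) {
  v <- suppressWarnings(tokenize_smiles(smiles))
  n <- sum(.is_atom_token(v$tokens))
  # bracket hydrogens like [H] are not heavy atoms
  n - sum(grepl("^\\[[0-9]*H[H0-9+@-]*\\]$", v$tokens))
}
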