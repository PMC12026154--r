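# Deterministic in-silico point mutagenesis by side-chain truncation.
#
# A mutation is applied only when the target side chain is an atom subset of
# the source side chain (after the C->S sulfur-for-oxygen swap), so no
# rotamer search is needed and every kept atom retains its coordinates.
# This covers the Mus m 1 stability mutants Y120F, Y120A, C138A and C138S
# and any X->A / X->G truncation.

#' Specify a single-point mutation
#'
#' @param chain chain identifier (single character).
#' @param res_seq residue number (PDB numbering).
#' @param wt one-letter code of the wild-type residue (checked against the
#'   model).
#' @param target one-letter code of the target residue.
#' @return object of class `mutation_spec`
#' @export
mutation_spec <- function(chain, res_seq, wt, target) {
  wt <- toupper(wt); target <- toupper(target)
  if (!wt %in% names(.aa_three) || !target %in% names(.aa_three))
    stop("unknown one-letter amino-acid code")
  if (wt == target) stop("mutation target equals wild-type residue")
  structure(list(chain = chain, res_seq = as.integer(res_seq),
                 wt = wt, target = target),
            class = "mutation_spec")
}

#' Parse a mutation string like "A:120:Y>F"
#' @param text string `chain:res_seq:WT>TARGET`
#' @return a [mutation_spec()]
#' @export
parse_mutation <- function(text) {
  m <- regmatches(text, regexec("^([A-Za-z0-9]):([0-9]+):([A-Z])>([A-Z])$",
                                text))[[1]]
  if (length(m) != 5) stop("cannot parse mutation '", text,
                           "'; expected chain:resseq:X>Y, e.g. A:120:Y>F")
  mutation_spec(m[2], as.integer(m[3]), m[4], m[5])
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("%s%d%s (chain %s)\n", x$wt, x$res_seq, x$target, x$chain))
  invisible(x)
}

#' Apply a single-point mutation to a structure model
#'
#' The mutated residue keeps its backbone and the side-chain atoms shared
#' with the target residue; surplus atoms are deleted.  For Cys->Ser the SG
#' atom is renamed OG (element S->O) and the CB-OG bond rescaled to 1.41
#' Angstrom along the existing CB->SG direction.  Any hydrogens on the
#' mutated residue are removed (rebuild them with
#' [add_semi_essential_hydrogens()]).  All other atoms are untouched.
#'
#' @param model a `structure_model`
#' @param spec a [mutation_spec()] or mutation string (see
#'   [parse_mutation()])
#' @return the mutated `structure_model`
#' @export
apply_mutation <- function(model, spec) {
  stopifnot(inherits(model, "structure_model"))
  if (is.character(spec)) spec <- parse_mutation(spec)
  stopifnot(inherits(spec, "mutation_spec"))
  idx <- residue_index(model, spec$chain, spec$res_seq)
  if (!length(idx))
    stop("no residue ", spec$res_seq, " in chain ", spec$chain)
  at <- model$atoms
  rn <- at$res_name[idx[1]]
  if (rn != .aa_three[[spec$wt]])
    stop("residue ", spec$chain, ":", spec$res_seq, " is ", rn,
         ", not ", .aa_three[[spec$wt]])
  target3 <- .aa_three[[spec$target]]
  # drop stale hydrogens of the residue first
  hyd <- idx[at$element[idx] == "H"]
  sc_idx <- setdiff(idx[!(at$name[idx] %in% c(.backbone_atoms, "OXT"))], hyd)
  sc_names <- at$name[sc_idx]
  target_sc <- .side_chain_atoms[[target3]]
  rename <- character(0)
  if (rn == "CYS" && target3 == "SER") rename <- c(SG = "OG")
  eff_names <- sc_names
  if (length(rename)) {
    hit <- eff_names %in% names(rename)
    eff_names[hit] <- rename[eff_names[hit]]
  }
  if (!all(target_sc %in% eff_names))
    stop("unsupported mutation ", spec$wt, spec$res_seq, spec$target,
         ": target side chain is not an atom subset of the source ",
         "(missing ", paste(setdiff(target_sc, eff_names), collapse = ", "),
         "); use an external rotamer/mutagenesis tool for this substitution")
  drop <- c(sc_idx[!(eff_names %in% target_sc)], hyd)
  if (length(rename)) {
    for (k in seq_along(rename)) {
      i_old <- sc_idx[match(names(rename)[k], sc_names)]
      if (is.na(i_old) || i_old %in% drop) next
      at$name[i_old] <- rename[[k]]
      at$element[i_old] <- substr(rename[[k]], 1, 1)
      if (rn == "CYS" && target3 == "SER") {
        cb <- idx[match("CB", at$name[idx])]
        v <- c(at$x[i_old] - at$x[cb], at$y[i_old] - at$y[cb],
               at$z[i_old] - at$z[cb])
        v <- vunit(v) * 1.41
        at$x[i_old] <- at$x[cb] + v[1]
        at$y[i_old] <- at$y[cb] + v[2]
        at$z[i_old] <- at$z[cb] + v[3]
      }
    }
  }
  at$res_name[idx] <- target3
  if (length(drop)) at <- at[-drop, ]
  structure_model(at)
}
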