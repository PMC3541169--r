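#' Published per-phylum distribution of PG metabolism genes
#'
#' The printed survey of 1,644 genomes (1,398 Bacteria across 21 phyla plus
#' an unclassified bin, 101 Archaea, 103 Viruses, 42 Eukaryota): for each
#' group, the number of genomes screened and how many carry at least one
#' gene of each CAZy family, plus how many carry the complete minimal
#' 3-gene set.  Values are stored exactly as printed, including the table's
#' internal quirks (the per-phylum complete-set column does not total the
#' headline 1,260; Chloroflexi is listed with n = 14), which are preserved
#' rather than reconciled.
#'
#' @return A tibble with columns `level` ("domain" or "phylum"), `name`,
#'   `n`, one count column per family in [pg_families()], and
#'   `complete_set`.
#' @export
fixture_table1 <- function() {
  dm <- function(name, n, ...) c(list(level = "domain", name = name, n = n), list(...))
  ph <- function(name, n, ...) c(list(level = "phylum", name = name, n = n), list(...))
  rows <- list(
    dm("Archaea",    101, GT28 = 4,    GT51 = 0,    GH23 = 0,    GH25 = 1,   GH73 = 1,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 0),
    dm("Viruses",    103, GT28 = 0,    GT51 = 0,    GH23 = 2,    GH25 = 1,   GH73 = 0,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 0),
    dm("Eukaryota",   42, GT28 = 5,    GT51 = 2,    GH23 = 3,    GH25 = 5,   GH73 = 0,   GH102 = 0,   GH103 = 1,   GH104 = 0,  complete_set = 1),
    dm("Bacteria",  1398, GT28 = 1342, GT51 = 1284, GH23 = 1224, GH25 = 419, GH73 = 707, GH102 = 467, GH103 = 528, GH104 = 95, complete_set = 1260),
    ph("Actinobacteria",              136, GT28 = 134, GT51 = 135, GH23 = 130, GH25 = 77,  GH73 = 8,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 133),
    ph("Aquificae",                     9, GT28 = 9,   GT51 = 9,   GH23 = 9,   GH25 = 0,   GH73 = 3,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 9),
    ph("Bacteroides-Chlorobi",         59, GT28 = 58,  GT51 = 59,  GH23 = 53,  GH25 = 25,  GH73 = 40,  GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 57),
    ph("Chlamydia",                    27, GT28 = 27,  GT51 = 0,   GH23 = 0,   GH25 = 0,   GH73 = 0,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 0),
    ph("Chloroflexi",                  14, GT28 = 9,   GT51 = 9,   GH23 = 9,   GH25 = 1,   GH73 = 0,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 9),
    ph("Cyanobacteria",                42, GT28 = 42,  GT51 = 40,  GH23 = 32,  GH25 = 2,   GH73 = 7,   GH102 = 19,  GH103 = 0,   GH104 = 23, complete_set = 32),
    ph("Deferribacteres",               3, GT28 = 3,   GT51 = 3,   GH23 = 3,   GH25 = 0,   GH73 = 0,   GH102 = 0,   GH103 = 3,   GH104 = 0,  complete_set = 3),
    ph("Deinococcus-Thermus",          13, GT28 = 13,  GT51 = 13,  GH23 = 10,  GH25 = 0,   GH73 = 0,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 10),
    ph("Dictyoglomi",                   2, GT28 = 2,   GT51 = 2,   GH23 = 0,   GH25 = 0,   GH73 = 0,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 0),
    ph("Elusimicrobia",                 2, GT28 = 2,   GT51 = 2,   GH23 = 1,   GH25 = 0,   GH73 = 0,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 1),
    ph("Fibrobacteres-Acidobacteria",   7, GT28 = 6,   GT51 = 6,   GH23 = 7,   GH25 = 0,   GH73 = 2,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 6),
    ph("Firmicutes",                  318, GT28 = 315, GT51 = 314, GH23 = 264, GH25 = 189, GH73 = 256, GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 309),
    ph("Fusobacteria",                  5, GT28 = 5,   GT51 = 5,   GH23 = 3,   GH25 = 3,   GH73 = 2,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 5),
    ph("Nitrospirae",                   2, GT28 = 2,   GT51 = 2,   GH23 = 2,   GH25 = 0,   GH73 = 0,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 2),
    ph("Planctomycetes",                6, GT28 = 3,   GT51 = 0,   GH23 = 0,   GH25 = 0,   GH73 = 0,   GH102 = 1,   GH103 = 0,   GH104 = 0,  complete_set = 0),
    ph("Proteobacteria",              673, GT28 = 664, GT51 = 644, GH23 = 658, GH25 = 121, GH73 = 370, GH102 = 442, GH103 = 524, GH104 = 72, complete_set = 644),
    ph("Spirochaetes",                 27, GT28 = 27,  GT51 = 26,  GH23 = 26,  GH25 = 1,   GH73 = 11,  GH102 = 4,   GH103 = 0,   GH104 = 0,  complete_set = 26),
    ph("Synergistetes",                 3, GT28 = 3,   GT51 = 2,   GH23 = 3,   GH25 = 0,   GH73 = 0,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 2),
    ph("Tenericutes",                  32, GT28 = 0,   GT51 = 0,   GH23 = 0,   GH25 = 0,   GH73 = 0,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 0),
    ph("Thermotogae",                  11, GT28 = 11,  GT51 = 10,  GH23 = 10,  GH25 = 0,   GH73 = 8,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 10),
    ph("Verrucomicrobia",               4, GT28 = 4,   GT51 = 1,   GH23 = 2,   GH25 = 0,   GH73 = 0,   GH102 = 0,   GH103 = 0,   GH104 = 0,  complete_set = 0),
    ph("Unclassified",                  3, GT28 = 3,   GT51 = 2,   GH23 = 2,   GH25 = 0,   GH73 = 0,   GH102 = 1,   GH103 = 1,   GH104 = 0,  complete_set = 2)
  )
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

#' Published confusion counts for the 3-gene set and the GT51 marker
#'
#' The headline counts of the bacterial screen: 1,260 of 1,398 Bacteria
#' carry the complete 3-gene set, all with literature-confirmed PG; the 138
#' set-negative genomes split into 84 PG-absent, 24 PG-present and 30 with
#' no literature information; 114 Bacteria lack GT51, of which 5 are
#' PG-producing.
#'
#' @return A named list of integer constants: `set_positive_total`,
#'   `set_negative_total`, `set_negative_pg_absent`,
#'   `set_negative_pg_present`, `set_negative_pg_unknown`,
#'   `gt51_negative_total`, `gt51_negative_pg_present`.
#' @export
fixture_confusion_counts <- function() {
  list(
    set_positive_total = 1260L,
    set_negative_total = 138L,
    set_negative_pg_absent = 84L,
    set_negative_pg_present = 24L,
    set_negative_pg_unknown = 30L,
    gt51_negative_total = 114L,
    gt51_negative_pg_present = 5L
  )
}
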