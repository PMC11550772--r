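.materials_order <- c(
  "graphene", "graphane", "alpha-graphyne", "beta-graphyne", "gamma-graphyne",
  "gamma-graphdiyne", "silicene", "germanene", "boron-nitride",
  "hexagonal-bilayer-silica", "haeckelite-silica", "MoS2", "WS2")

# materials whose primitive cell is hexagonal: |a1| = |a2|, 120 degrees
.hexagonal_materials <- c(
  "graphene", "graphane", "alpha-graphyne", "beta-graphyne", "gamma-graphyne",
  "gamma-graphdiyne", "silicene", "germanene", "boron-nitride",
  "hexagonal-bilayer-silica", "MoS2", "WS2")

.materials_env <- new.env(parent = emptyenv())

#' List the built-in single-layer materials
#'
#' The library ships thirteen curated single-layer materials: graphene,
#' graphane, the alpha/beta/gamma graphyne polymorphs, gamma-graphdiyne,
#' silicene, germanene, hexagonal boron nitride, the hexagonal and
#' Stone-Wales (haeckelite) silica bilayers, MoS2 and WS2.
#'
#' @return character vector of 13 material identifiers in a fixed order.
#' @export
#' @examples
#' list_materials()
list_materials <- function() .materials_order

#' Retrieve a built-in material unit cell
#'
#' Hexagonal materials use the convention `|a1| = |a2|` with 120 degrees
#' between the lattice vectors; basis sites are Cartesian with the layer
#' mid-plane at z = 0, so an atom's z coordinate is its height inside the
#' layer.  Geometries come from standard literature values recorded in each
#' cell's `source_note`.
#'
#' @param name one of [list_materials()].
#' @return a validated [unit_cell_2d()] object.
#' @export
#' @examples
#' get_material("MoS2")
get_material <- function(name) {
  if (!name %in% .materials_order)
    stop("unknown material '", name, "'; valid names are: ",
         paste(.materials_order, collapse = ", "))
  if (is.null(.materials_env[[name]])) {
    path <- system.file("extdata", "materials", paste0(name, ".cell"),
                        package = "nanoroll", mustWork = TRUE)
    .materials_env[[name]] <- validate_user_cell(path)
  }
  .materials_env[[name]]
}

#' Is a built-in material hexagonal?
#' @param name material identifier.
#' @return logical.
#' @export
is_hexagonal_material <- function(name) name %in% .hexagonal_materials
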