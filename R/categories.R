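#' Food-access categories
#'
#' The ten-way classification of food-environment venue types used throughout
#' the package, indexed `A1` to `A10`: low-access stores, grocery stores,
#' supercenters, club stores, convenience stores, specialized food stores,
#' full-service restaurants, fast-food restaurants, school food service, and
#' direct farm sales.
#'
#' @return Character vector of the ten category codes, named by a short label.
#' @export
#' @examples
#' food_access_categories()
food_access_categories <- function() {
  stats::setNames(
    paste0("A", 1:10),
    c("low_access_stores", "grocery_stores", "supercenters", "club_stores",
      "convenience_stores", "specialized_food_stores",
      "full_service_restaurants", "fast_food_restaurants",
      "school_food_service", "direct_farm_sales")
  )
}

# closed per-category vocabulary for synthetic POI descriptions; terms are
# disjoint from .mismatch_vocab so a non-matching text scores cosine 0
.category_vocab <- list(
  A1 = c("corner", "discount", "limited", "pantry", "dollar", "outlet"),
  A2 = c("grocery", "produce", "market", "dairy", "bakery", "deli"),
  A3 = c("supercenter", "hypermarket", "bulk", "aisles", "warehouse", "cart"),
  A4 = c("club", "membership", "wholesale", "pallet", "crate", "case"),
  A5 = c("convenience", "snack", "soda", "candy", "gas", "quick"),
  A6 = c("specialty", "organic", "imported", "cheese", "spice", "tea"),
  A7 = c("restaurant", "dinner", "menu", "waiter", "grill", "bistro"),
  A8 = c("burger", "fries", "fastfood", "drivethru", "pizza", "shake"),
  A9 = c("school", "cafeteria", "lunch", "tray", "student", "canteen"),
  A10 = c("farm", "orchard", "stand", "harvest", "pickyourown", "csa")
)

.mismatch_vocab <- c(
  "traffic", "weather", "football", "concert", "meeting", "airport",
  "homework", "movie", "rain", "sunset", "gym", "parade"
)
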