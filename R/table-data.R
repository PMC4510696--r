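# Frozen transcriptions of the published miRNA enrichment tables for the
# three KRAS-isogenic CRC lines (DKO-1 mutant, DKs-8 wild-type, DLD-1
# parental), split into the seven set-partition categories, plus the
# printed absolute miR-100 copy numbers from the Transwell co-culture
# qPCR experiment. Used by write_fixture_tables() and the acceptance
# checks.

.cell_enriched_mirnas <- list(
  `DKO-1` = c(
    "hsa-miR-548u",
    "hsa-miR-16-1-3p",
    "hsa-miR-33a-3p",
    "hsa-miR-33a-5p",
    "hsa-miR-31-5p",
    "hsa-miR-181b-3p",
    "hsa-miR-450a-5p",
    "hsa-miR-424-5p",
    "hsa-miR-9-5p",
    "hsa-miR-219-5p",
    "hsa-miR-190a",
    "hsa-miR-573",
    "hsa-miR-30d-3p",
    "hsa-miR-204-5p",
    "hsa-miR-1226-3p",
    "hsa-miR-499a-5p",
    "hsa-miR-450b-5p",
    "hsa-miR-499b-3p",
    "hsa-miR-3662",
    "hsa-miR-20a-3p",
    "hsa-miR-27b-5p",
    "hsa-miR-5701",
    "hsa-miR-4677-3p",
    "hsa-let-7i-5p",
    "hsa-miR-331-3p",
    "hsa-miR-31-3p",
    "hsa-miR-651",
    "hsa-miR-1306-5p",
    "hsa-miR-147b",
    "hsa-miR-3611",
    "hsa-miR-1305",
    "hsa-miR-148a-3p",
    "hsa-miR-27b-3p",
    "hsa-miR-1306-3p",
    "hsa-miR-374b-3p",
    "hsa-miR-1260b",
    "hsa-miR-3940-3p",
    "hsa-miR-200c-5p",
    "hsa-miR-548ar-3p"
  ),
  `DKs-8` = c(
    "hsa-miR-132-5p",
    "hsa-miR-484",
    "hsa-miR-374a-5p",
    "hsa-miR-1180",
    "hsa-miR-1307-3p",
    "hsa-miR-200a-5p",
    "hsa-miR-548o-3p",
    "hsa-miR-149-5p",
    "hsa-miR-3615",
    "hsa-miR-100-5p",
    "hsa-miR-197-3p",
    "hsa-miR-378a-5p",
    "hsa-let-7a-3p"
  ),
  `DLD-1` = c(
    "hsa-miR-141-3p",
    "hsa-miR-26b-5p",
    "hsa-miR-24-3p",
    "hsa-miR-3074-5p",
    "hsa-miR-15a-5p",
    "hsa-miR-27a-3p",
    "hsa-miR-3613-5p",
    "hsa-miR-30b-5p",
    "hsa-miR-29a-3p",
    "hsa-miR-301a-5p",
    "hsa-let-7i-3p",
    "hsa-miR-185-5p",
    "hsa-let-7g-5p",
    "hsa-miR-23b-3p",
    "hsa-miR-22-3p"
  ),
  `DKO-1&DKs-8` = c(
    "hsa-miR-141-5p",
    "hsa-miR-582-5p"
  ),
  `DKO-1&DLD-1` = c(
    "hsa-miR-556-3p",
    "hsa-miR-374a-3p",
    "hsa-miR-106b-5p",
    "hsa-miR-17-3p",
    "hsa-miR-24-1-5p",
    "hsa-miR-340-3p"
  ),
  `DLD-1&DKs-8` = c(
    "hsa-miR-24-2-5p",
    "hsa-miR-106a-5p",
    "hsa-miR-30e-5p",
    "hsa-miR-107",
    "hsa-miR-429",
    "hsa-miR-98-5p",
    "hsa-miR-425-5p",
    "hsa-miR-140-5p",
    "hsa-miR-93-5p",
    "hsa-miR-210",
    "hsa-miR-126-3p",
    "hsa-miR-194-5p",
    "hsa-miR-29b-3p",
    "hsa-miR-15b-5p",
    "hsa-miR-362-5p",
    "hsa-miR-27a-5p",
    "hsa-miR-454-3p",
    "hsa-miR-452-5p",
    "hsa-miR-196b-5p"
  ),
  `DKO-1&DLD-1&DKs-8` = c(
    "hsa-miR-32-5p",
    "hsa-miR-582-3p",
    "hsa-miR-542-3p",
    "hsa-miR-96-5p",
    "hsa-miR-101-3p",
    "hsa-miR-18a-5p",
    "hsa-miR-3529-3p",
    "hsa-miR-7-5p",
    "hsa-miR-19a-3p",
    "hsa-miR-142-3p",
    "hsa-miR-20a-5p",
    "hsa-miR-32-3p",
    "hsa-miR-130b-5p",
    "hsa-miR-1278",
    "hsa-miR-7-1-3p",
    "hsa-miR-590-3p",
    "hsa-miR-4473",
    "hsa-miR-17-5p",
    "hsa-miR-103a-3p",
    "hsa-miR-103b",
    "hsa-miR-19b-3p",
    "hsa-miR-340-5p",
    "hsa-miR-200a-3p",
    "hsa-miR-34a-5p",
    "hsa-miR-372"
  )
)

.exosome_enriched_mirnas <- list(
  `DKO-1` = c(
    "hsa-miR-139-5p",
    "hsa-miR-3178",
    "hsa-miR-151b",
    "hsa-miR-125b-1-3p",
    "hsa-miR-193b-3p",
    "hsa-miR-935",
    "hsa-miR-130b-3p",
    "hsa-miR-628-3p",
    "hsa-miR-139-3p",
    "hsa-let-7d-3p",
    "hsa-miR-589-3p",
    "hsa-miR-4532",
    "hsa-miR-451a",
    "hsa-miR-6087",
    "hsa-miR-151a-5p",
    "hsa-miR-940",
    "hsa-miR-222-3p",
    "hsa-miR-766-5p",
    "hsa-miR-505-5p",
    "hsa-miR-3187-3p",
    "hsa-miR-125a-3p",
    "hsa-miR-3679-5p",
    "hsa-miR-4436b-3p",
    "hsa-miR-4787-3p",
    "hsa-miR-2277-3p",
    "hsa-miR-361-5p",
    "hsa-miR-1293",
    "hsa-miR-3183",
    "hsa-miR-3162-5p",
    "hsa-miR-642a-3p",
    "hsa-miR-642b-5p",
    "hsa-miR-197-5p",
    "hsa-miR-324-3p",
    "hsa-miR-145-3p",
    "hsa-miR-3182",
    "hsa-miR-3127-3p",
    "hsa-miR-3127-5p",
    "hsa-miR-4728-3p",
    "hsa-miR-3184-5p",
    "hsa-miR-125b-5p",
    "hsa-miR-186-5p",
    "hsa-miR-1",
    "hsa-miR-100-5p",
    "hsa-miR-423-3p",
    "hsa-miR-766-3p",
    "hsa-miR-4753-5p",
    "hsa-miR-145-5p",
    "hsa-miR-4724-5p",
    "hsa-miR-373-3p",
    "hsa-miR-223-5p",
    "hsa-miR-1307-5p",
    "hsa-miR-1914-3p",
    "hsa-miR-3121-3p",
    "hsa-miR-3613-3p",
    "hsa-miR-205-5p",
    "hsa-miR-98-3p",
    "hsa-miR-23a-3p",
    "hsa-miR-3124-5p",
    "hsa-miR-3656",
    "hsa-miR-3918",
    "hsa-miR-4449",
    "hsa-miR-378c",
    "hsa-miR-3138",
    "hsa-miR-1910",
    "hsa-miR-3174",
    "hsa-miR-4466",
    "hsa-miR-3679-3p",
    "hsa-miR-3200-5p",
    "hsa-miR-6511b-5p",
    "hsa-miR-1247-5p",
    "hsa-miR-22-3p",
    "hsa-miR-877-5p",
    "hsa-miR-4687-3p",
    "hsa-miR-1292-5p",
    "hsa-miR-181c-5p",
    "hsa-miR-6131",
    "hsa-miR-6513-5p",
    "hsa-miR-3661",
    "hsa-miR-132-3p",
    "hsa-miR-214-3p",
    "hsa-miR-574-3p",
    "hsa-miR-3190-3p",
    "hsa-miR-326",
    "hsa-miR-3191-5p",
    "hsa-miR-3198",
    "hsa-miR-3928",
    "hsa-miR-629-3p",
    "hsa-miR-4489",
    "hsa-miR-4700-5p",
    "hsa-miR-5006-5p",
    "hsa-miR-5088",
    "hsa-miR-2110",
    "hsa-miR-3911",
    "hsa-miR-3146"
  ),
  `DKs-8` = c(
    "hsa-miR-1224-5p",
    "hsa-let-7b-5p",
    "hsa-miR-155-5p",
    "hsa-let-7c",
    "hsa-let-7a-5p",
    "hsa-miR-146b-5p",
    "hsa-miR-4647",
    "hsa-miR-4494",
    "hsa-miR-711",
    "hsa-miR-1263"
  ),
  `DLD-1` = c(
    "hsa-miR-1226-5p",
    "hsa-miR-4745-5p",
    "hsa-miR-4435",
    "hsa-miR-939-5p",
    "hsa-miR-409-3p",
    "hsa-miR-1304-3p"
  ),
  `DKO-1&DKs-8` = c(
    "hsa-miR-146a-5p",
    "hsa-miR-4508",
    "hsa-miR-224-5p",
    "hsa-miR-4429",
    "hsa-miR-222-5p",
    "hsa-miR-629-5p",
    "hsa-miR-4492",
    "hsa-miR-3653",
    "hsa-miR-320a",
    "hsa-miR-1290",
    "hsa-miR-1262",
    "hsa-miR-5010-5p",
    "hsa-miR-204-3p",
    "hsa-miR-4461",
    "hsa-miR-5187-5p"
  ),
  `DKO-1&DLD-1` = c(
    "hsa-miR-483-5p",
    "hsa-miR-4658",
    "hsa-miR-4758-5p",
    "hsa-miR-492",
    "hsa-miR-5001-5p",
    "hsa-miR-371a-5p",
    "hsa-miR-1323",
    "hsa-miR-371b-3p",
    "hsa-miR-501-3p",
    "hsa-miR-4446-3p",
    "hsa-miR-6511a-5p",
    "hsa-miR-30a-3p",
    "hsa-miR-4727-3p"
  ),
  `DLD-1&DKs-8` = c(
    "hsa-miR-28-3p",
    "hsa-miR-3934-5p"
  ),
  `DKO-1&DLD-1&DKs-8` = c(
    "hsa-miR-658",
    "hsa-miR-320d",
    "hsa-miR-4792",
    "hsa-miR-1246",
    "hsa-miR-320e",
    "hsa-miR-4516",
    "hsa-miR-320b",
    "hsa-miR-4488",
    "hsa-miR-1291",
    "hsa-miR-320c",
    "hsa-miR-4634",
    "hsa-miR-3605-5p",
    "hsa-miR-4741",
    "hsa-miR-3591-3p",
    "hsa-miR-122-5p",
    "hsa-miR-486-3p",
    "hsa-miR-184",
    "hsa-miR-223-3p",
    "hsa-miR-3651",
    "hsa-miR-486-5p",
    "hsa-miR-3180",
    "hsa-miR-3180-3p",
    "hsa-miR-3168",
    "hsa-miR-4497",
    "hsa-miR-423-5p",
    "hsa-miR-3184-3p",
    "hsa-miR-150-5p",
    "hsa-miR-664a-5p",
    "hsa-miR-182-5p"
  )
)

# condition labels: DKs-8 recipient cells cultured with DKO-1 donors
# pre-treated with miR-100 antagomir (AI-100), control antagomir
# (AI-CTL), or grown without donor cells.
.mir100_copy_numbers <- data.frame(
  condition = c("AI-100", "AI-CTL", "no donor"),
  copies = c(357.23, 442.58, 329.48),
  sem = c(16.65, 12.59, 13.62),
  stringsAsFactors = FALSE
)
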