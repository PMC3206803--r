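TY  - JOUR
AN  - DEMO-01
TI  - Grazing pressure on coral reefs along a depth gradient
AB  - We surveyed benthic assemblages in coral reefs. Petrus albus dominated shallow sites.
KW  - herbivory
KW  - coral reefs
PY  - 1995
ER  -

TY  - JOUR
AN  - DEMO-02
TI  - Seasonal dynamics of kelp forest communities
AB  - Limnus acuta and Limnella gracilis were abundant in the kelp forest understory.
KW  - kelp forests
PY  - 2003
ER  -

TY  - JOUR
AN  - DEMO-03
TI  - Recruitment of Virida laeta in seagrass beds
AB  - Settlement of Virida laeta was measured in seagrass meadows over two seasons.
KW  - recruitment
PY  - 2008
ER  -

TY  - JOUR
AN  - DEMO-04
TI  - Nutrient cycling in mangrove forests
AB  - Sediment cores from mangrove forests showed strong seasonal variation.
KW  - nutrients
PY  - 1999
ER  -

TY  - JOUR
AN  - DEMO-05
TI  - Coral recruitment and larval supply
AB  - Larval supply of corals was measured offshore with light traps.
KW  - larval ecology
PY  - 2001
ER  -

TY  - JOUR
AN  - DEMO-06
TI  - Vetustus primus in coral reef sediments
AB  - The species Vetustus primus was recorded from coral reef sediments.
KW  - sediments
PY  - 2006
ER  -

TY  - JOUR
AN  - DEMO-07
TI  - A study without a publication year tag
AB  - This malformed entry lacks a year and must be skipped by the reader.
KW  - malformed
ER  -

TY  - JOUR
AN  - DEMO-08
TI  - Trophic interactions in seagrass beds
AB  - Granus magna preyed on Limnus lenta within seagrass beds.
KW  - predation
KW  - food webs
PY  - 2007
ER  -

TY  - JOUR
AN  - DEMO-09
TI  - Long-term change in coral-reef fish assemblages
AB  - Decadal surveys revealed declines across the reef.
ID  - keywords plus coral reefs
KW  - time series
PY  - 2009
ER  -

TY  - JOUR
AN  - DEMO-10
TI  - Viridella tenuis beds in a temperate estuary
AB  - Dense beds of Viridella tenuis were mapped. No ecosystem phrase occurs in this record.
KW  - mapping
PY  - 1988
ER  -
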