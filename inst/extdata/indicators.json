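[
  {
    "id": "PE1",
    "level": "farm",
    "dimension": "economic",
    "name": "Economic growth - added value per farm",
    "unit": "usd",
    "polarity": "higher-is-better",
    "operands": ["n_beef_cattle", "avg_selling_price", "n_farms"],
    "edges": [1162.43, 1929.75, 2697.05, 3464.35, 4231.65, 4998.96]
  },
  {
    "id": "PE2",
    "level": "farm",
    "dimension": "economic",
    "name": "Income distribution - share of large-scale farms",
    "unit": "percent",
    "polarity": "higher-is-better",
    "operands": ["n_large_farms", "n_farms"],
    "edges": [0, 8, 16, 24, 32, 40]
  },
  {
    "id": "PE3",
    "level": "farm",
    "dimension": "economic",
    "name": "Self-sufficiency - beef supply versus demand",
    "unit": "percent",
    "polarity": "higher-is-better",
    "operands": ["slaughter_capacity", "avg_carcass_weight", "consumption_per_capita", "population"],
    "edges": [0, 20, 40, 60, 80, 100]
  },
  {
    "id": "PE4",
    "level": "farm",
    "dimension": "economic",
    "name": "Investment cost - share of insured beef cattle",
    "unit": "percent",
    "polarity": "higher-is-better",
    "operands": ["n_insured_cattle", "n_beef_cattle"],
    "edges": [0, 20, 40, 60, 80, 100]
  },
  {
    "id": "PS1",
    "level": "farm",
    "dimension": "social",
    "name": "Employees in the enterprise - farmers per farm",
    "unit": "ratio",
    "polarity": "higher-is-better",
    "operands": ["n_farmers", "n_farms"],
    "edges": [0.51, 0.96, 1.41, 1.87, 2.32, 2.77]
  },
  {
    "id": "PS2",
    "level": "farm",
    "dimension": "social",
    "name": "Gender equality - share of female farmers",
    "unit": "percent",
    "polarity": "higher-is-better",
    "operands": ["n_female_farmers", "n_farmers"],
    "edges": [0, 10, 20, 30, 40, 50]
  },
  {
    "id": "PS3",
    "level": "farm",
    "dimension": "social",
    "name": "Education - share of farmers above senior high school",
    "unit": "percent",
    "polarity": "higher-is-better",
    "operands": ["n_educated_farmers", "n_farmers"],
    "edges": [0, 20, 40, 60, 80, 100]
  },
  {
    "id": "PS4",
    "level": "farm",
    "dimension": "social",
    "name": "Animal welfare - share of beef cattle infected",
    "unit": "percent",
    "polarity": "lower-is-better",
    "operands": ["n_infected_cattle", "n_beef_cattle"],
    "edges": [0, 20, 40, 60, 80, 100]
  },
  {
    "id": "PL1",
    "level": "farm",
    "dimension": "environmental",
    "name": "Water consumption cost for livestock activities",
    "unit": "usd",
    "polarity": "lower-is-better",
    "operands": ["water_cost_per_head_month", "n_beef_cattle"],
    "edges": [178440.63, 347082.94, 515725.24, 684367.55, 853009.86, 1021652.16]
  },
  {
    "id": "PL2",
    "level": "farm",
    "dimension": "environmental",
    "name": "Energy used - electricity cost for livestock activities",
    "unit": "usd",
    "polarity": "lower-is-better",
    "operands": ["kwh_per_head_month", "n_beef_cattle", "electricity_price_per_kwh"],
    "edges": [503.65, 1538.88, 2574.11, 3609.34, 4644.57, 5679.80]
  },
  {
    "id": "PL3",
    "level": "farm",
    "dimension": "environmental",
    "name": "Global warming - fuel cost of farm-to-slaughterhouse transport",
    "unit": "usd",
    "polarity": "lower-is-better",
    "operands": ["distance_km", "fuel_km_per_litre", "fuel_price_per_litre"],
    "edges": [345.34, 773.96, 1122.58, 1466.55, 1811.88, 2157.22]
  },
  {
    "id": "RE1",
    "level": "slaughterhouse",
    "dimension": "economic",
    "name": "Economic growth - added value per slaughterhouse labourer",
    "unit": "usd",
    "polarity": "higher-is-better",
    "operands": ["avg_carcass_weight", "selling_price_per_kg", "selling_price_per_head", "slaughter_capacity", "n_labor"],
    "edges": [9533.17, 14299.81, 27646.26, 40992.72, 54339.17, 67685.63]
  },
  {
    "id": "RE2",
    "level": "slaughterhouse",
    "dimension": "economic",
    "name": "Self-sufficiency - beef supply versus demand",
    "unit": "percent",
    "polarity": "higher-is-better",
    "operands": ["slaughter_capacity", "avg_carcass_weight", "consumption_per_capita", "population"],
    "edges": [0, 20, 40, 60, 80, 100]
  },
  {
    "id": "RS1",
    "level": "slaughterhouse",
    "dimension": "social",
    "name": "Employees in the enterprise - employees per slaughterhouse",
    "unit": "ratio",
    "polarity": "higher-is-better",
    "operands": ["n_employees", "n_slaughterhouses"],
    "edges": [0.50, 3.8, 7.1, 10.4, 13.7, 17]
  },
  {
    "id": "RS2",
    "level": "slaughterhouse",
    "dimension": "social",
    "name": "Gender equality - share of female slaughterhouse employees",
    "unit": "percent",
    "polarity": "higher-is-better",
    "operands": ["n_female_employees", "n_employees"],
    "edges": [0, 10, 20, 30, 40, 50]
  },
  {
    "id": "RS3",
    "level": "slaughterhouse",
    "dimension": "social",
    "name": "Education - share of employees above senior high school",
    "unit": "percent",
    "polarity": "higher-is-better",
    "operands": ["n_educated_employees", "n_employees"],
    "edges": [0, 20, 40, 60, 80, 100]
  },
  {
    "id": "RS4",
    "level": "slaughterhouse",
    "dimension": "social",
    "name": "Animal welfare - share of slaughtered cattle infected",
    "unit": "percent",
    "polarity": "lower-is-better",
    "operands": ["n_infected_cattle", "slaughter_capacity"],
    "edges": [0, 20, 40, 60, 80, 100]
  },
  {
    "id": "RL1",
    "level": "slaughterhouse",
    "dimension": "environmental",
    "name": "Water consumption cost for slaughter activities",
    "unit": "usd",
    "polarity": "lower-is-better",
    "operands": ["water_cost_per_month"],
    "edges": [25.7, 103.45, 181.19, 258.94, 336.68, 414.43]
  },
  {
    "id": "RL2",
    "level": "slaughterhouse",
    "dimension": "environmental",
    "name": "Energy used - electricity cost for slaughter activities",
    "unit": "usd",
    "polarity": "lower-is-better",
    "operands": ["kwh_per_month", "electricity_price_per_kwh"],
    "edges": [0, 84.03, 168.06, 252.09, 336.12, 420.16]
  },
  {
    "id": "RL3",
    "level": "slaughterhouse",
    "dimension": "environmental",
    "name": "Global warming - fuel cost of farm-to-slaughterhouse transport",
    "unit": "usd",
    "polarity": "lower-is-better",
    "operands": ["distance_km", "fuel_km_per_litre", "fuel_price_per_litre"],
    "edges": [345.34, 773.96, 1122.58, 1466.55, 1811.88, 2157.22]
  }
]
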