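# Default nutritional bounds per sex, derived from national dietary
# reference values for 18-60-year-old adults. Units: per_day bounds are
# kcal/day (energy), g/day (protein, fiber, alcohol), mg/day
# (cholesterol, calcium, iron, zinc) or ug/day (vitamin B12);
# percent_energy bounds are % of total dietary energy.
# The female iron range is shipped disabled: the observed female diet
# cannot reach it under the acceptability constraints, so it is only
# included on request to reproduce the infeasibility diagnostic.
male:
  energy:       {lb: 2400, ub: 2460, unit: per_day}
  protein:      {lb: 60,   ub: 92,   unit: per_day}
  total_fat:    {lb: 24.5, ub: 30.8, unit: percent_energy}
  sfa:          {lb: 7.0,  ub: 10.1, unit: percent_energy}
  pufa:         {lb: 4.8,  ub: 10.1, unit: percent_energy}
  cholesterol:  {lb: 250,  ub: 300,  unit: per_day}
  carbohydrate: {lb: 46.8, ub: 65.7, unit: percent_energy}
  total_sugar:  {lb: 10.4, ub: 16.3, unit: percent_energy}
  free_sugar:   {lb: 4.2,  ub: 5.5,  unit: percent_energy}
  fiber:        {lb: 24,   ub: 26,   unit: per_day}
  calcium:      {lb: 900,  ub: 1100, unit: per_day}
  iron:         {lb: 9,    ub: 11,   unit: per_day}
  zinc:         {lb: 11,   ub: 13,   unit: per_day}
  vitamin_b12:  {lb: 2,    ub: 3,    unit: per_day}
  alcohol:      {lb: 0,    ub: 0,    unit: per_day}
female:
  energy:       {lb: 1900, ub: 1982, unit: per_day}
  protein:      {lb: 52,   ub: 73,   unit: per_day}
  total_fat:    {lb: 24.1, ub: 31.3, unit: percent_energy}
  sfa:          {lb: 6.4,  ub: 10.4, unit: percent_energy}
  pufa:         {lb: 4.5,  ub: 10.4, unit: percent_energy}
  cholesterol:  {lb: 250,  ub: 300,  unit: per_day}
  carbohydrate: {lb: 46.0, ub: 66.7, unit: percent_energy}
  total_sugar:  {lb: 10.3, ub: 16.6, unit: percent_energy}
  free_sugar:   {lb: 4.0,  ub: 5.5,  unit: percent_energy}
  fiber:        {lb: 24,   ub: 26,   unit: per_day}
  calcium:      {lb: 900,  ub: 1100, unit: per_day}
  iron:         {lb: 17,   ub: 19,   unit: per_day, enabled: false}
  zinc:         {lb: 8,    ub: 10,   unit: per_day}
  vitamin_b12:  {lb: 2,    ub: 3,    unit: per_day}
policy:
  red_meat:       {lb: 10,  ub: 30}
  processed_meat: {lb: 0,   ub: 0}
  alcoholic:      {lb: 0,   ub: 0}
  fruit_veg:      {lb: 400, ub: 500}
  pulse:          {lb: 20,  ub: .inf}
  fish:           {lb: 20,  ub: .inf}
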