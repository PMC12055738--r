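# Default three-pillar configuration: 22 percentage-valued indicators,
# each its own equally weighted dimension. The split below is the
# package default, not an authoritative survey mapping; supply your own
# config for real analyses.
pillars:
  MHU:
    indicators:
      - anc_first_trimester
      - anc_four_visits
      - full_antenatal_care
      - iron_folic_100_days
      - neonatal_tetanus_protected
      - mcp_card_registered
      - pnc_mother_2_days
      - pnc_newborn_2_days
  WE:
    indicators:
      - household_decision_participation
      - owns_mobile_phone
      - owns_bank_account
      - hygienic_menstrual_protection
      - owns_house_or_land
      - literate_women
      - worked_paid_last_year
  DC:
    indicators:
      - institutional_birth
      - institutional_birth_public
      - skilled_birth_attendance
      - home_birth_skilled_attendant
      - birth_registered
      - postnatal_facility_stay_48h
      - delivery_by_caesarean_public
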