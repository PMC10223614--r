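<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic toy taxon model in the supported SBML subset: a glucose
     uptake, one conversion to biomass precursor plus acetate, an acetate
     secretion and a biomass reaction. Not derived from any database. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="toy_acetogen_synthetic">
    <listOfParameters>
      <parameter id="lb_uptake" value="-10"/>
      <parameter id="ub_default" value="1000"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="glc" compartment="c"/>
      <species id="acetate" compartment="c"/>
      <species id="bm" compartment="c"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_glc" reversible="true" lowerFluxBound="lb_uptake" upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="glc" stoichiometry="1"/>
        </listOfReactants>
      </reaction>
      <reaction id="CONV_glc" reversible="false">
        <listOfReactants>
          <speciesReference species="glc" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="bm" stoichiometry="0.05"/>
          <speciesReference species="acetate" stoichiometry="1.2"/>
        </listOfProducts>
      </reaction>
      <reaction id="EX_acetate" reversible="false">
        <listOfReactants>
          <speciesReference species="acetate" stoichiometry="1"/>
        </listOfReactants>
      </reaction>
      <reaction id="biomass_toy" reversible="false">
        <listOfReactants>
          <speciesReference species="bm" stoichiometry="1"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
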