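<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic miniature acetogen model (SBML L3V1 + FBC v2) used to
     exercise the SBML import path. Hand-written; not derived from any
     published reconstruction. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_acetogen_sbml" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="co2" compartment="c" fbc:chemicalFormula="CO2"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="h2" compartment="c" fbc:chemicalFormula="H2"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="nadh" compartment="c" fbc:chemicalFormula="H2"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="accoa" compartment="c" fbc:chemicalFormula="C2H4O2"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="ac" compartment="c" fbc:chemicalFormula="C2H4O2"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="atp" compartment="c" fbc:chemicalFormula="HO4P"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_free" value="-1000" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_free" value="1000" constant="true"/>
      <parameter id="lb_co2" value="-10" constant="true"/>
      <parameter id="lb_h2" value="-20" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_co2" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_co2" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="co2" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_h2" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_h2" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="h2" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_ac" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_free" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="ac" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="HYDA" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="h2" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="nadh" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="WLP" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="co2" stoichiometry="2" constant="true"/>
          <speciesReference species="nadh" stoichiometry="4" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="accoa" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="ACK" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="accoa" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="ac" stoichiometry="1" constant="true"/>
          <speciesReference species="atp" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="BIOMASS_a" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="accoa" stoichiometry="1" constant="true"/>
          <speciesReference species="atp" stoichiometry="3" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="BIOMASS_a"
                             fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
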