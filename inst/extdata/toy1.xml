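<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="TOY1" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="B" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="C" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="N" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="NH" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="P" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="D" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_uptake" value="-10" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_default" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_A" reversible="true" fast="false" fbc:lowerFluxBound="lb_uptake" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R1" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="g1"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R2" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
          <speciesReference species="NH" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
          <speciesReference species="N" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="g2"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R3" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
          <speciesReference species="N" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="P" stoichiometry="1" constant="true"/>
          <speciesReference species="NH" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="g3"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R4" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
          <speciesReference species="N" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="D" stoichiometry="1" constant="true"/>
          <speciesReference species="NH" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="g4"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="EX_P" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="P" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_D" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="D" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="BIOMASS" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="g3" fbc:label="g3"/>
      <fbc:geneProduct fbc:id="g4" fbc:label="g4"/>
    </fbc:listOfGeneProducts>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="BIOMASS" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
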