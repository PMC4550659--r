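<?xml version="1.0" encoding="UTF-8"?>
<!-- Subset profile of the DataCite Metadata Schema kernel-3, authored for
     this package: it covers the kernel elements the crosswalk emits
     (identifier, creators with ORCID nameIdentifiers, titles, publisher,
     publicationYear, alternateIdentifiers, relatedIdentifiers with the
     HasMetadata relation). It is a validation profile, not a copy of the
     full third-party schema. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           targetNamespace="http://datacite.org/schema/kernel-3"
           xmlns:dc="http://datacite.org/schema/kernel-3"
           elementFormDefault="qualified"
           attributeFormDefault="unqualified">

  <xs:simpleType name="nonEmptyString">
    <xs:restriction base="xs:string">
      <xs:minLength value="1"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="yearType">
    <xs:restriction base="xs:string">
      <xs:pattern value="[0-9]{4}"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="relationTypeType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="IsCitedBy"/>
      <xs:enumeration value="Cites"/>
      <xs:enumeration value="IsSupplementTo"/>
      <xs:enumeration value="IsSupplementedBy"/>
      <xs:enumeration value="IsPartOf"/>
      <xs:enumeration value="HasPart"/>
      <xs:enumeration value="IsDerivedFrom"/>
      <xs:enumeration value="IsSourceOf"/>
      <xs:enumeration value="HasMetadata"/>
      <xs:enumeration value="IsMetadataFor"/>
      <xs:enumeration value="IsDocumentedBy"/>
      <xs:enumeration value="Documents"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="resource">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="identifier">
          <xs:complexType>
            <xs:simpleContent>
              <xs:extension base="dc:nonEmptyString">
                <xs:attribute name="identifierType" use="required" fixed="DOI"/>
              </xs:extension>
            </xs:simpleContent>
          </xs:complexType>
        </xs:element>
        <xs:element name="creators">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="creator" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="creatorName" type="dc:nonEmptyString"/>
                    <xs:element name="nameIdentifier" minOccurs="0"
                                maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:simpleContent>
                          <xs:extension base="dc:nonEmptyString">
                            <xs:attribute name="nameIdentifierScheme"
                                          use="required"/>
                            <xs:attribute name="schemeURI" type="xs:anyURI"/>
                          </xs:extension>
                        </xs:simpleContent>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="titles">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="title" type="dc:nonEmptyString"
                          maxOccurs="unbounded"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="publisher" type="dc:nonEmptyString"/>
        <xs:element name="publicationYear" type="dc:yearType"/>
        <xs:element name="alternateIdentifiers" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="alternateIdentifier" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:simpleContent>
                    <xs:extension base="dc:nonEmptyString">
                      <xs:attribute name="alternateIdentifierType"
                                    use="required"/>
                    </xs:extension>
                  </xs:simpleContent>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="relatedIdentifiers" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="relatedIdentifier" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:simpleContent>
                    <xs:extension base="dc:nonEmptyString">
                      <xs:attribute name="relatedIdentifierType"
                                    use="required"/>
                      <xs:attribute name="relationType"
                                    type="dc:relationTypeType"
                                    use="required"/>
                      <xs:attribute name="relatedMetadataScheme"/>
                      <xs:attribute name="schemeURI" type="xs:anyURI"/>
                    </xs:extension>
                  </xs:simpleContent>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
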